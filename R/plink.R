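#' Write a genotype panel in PLINK format
#'
#' `format = "bed"` writes the binary triple `.bed`/`.bim`/`.fam` (SNP-major,
#' standard magic bytes); `format = "ped"` writes the text `.ped`/`.map`
#' dialect. The panel counts the A2 allele; in the `.bim`/`.map`, allele 1 is
#' written as the counted (A2) allele, matching the reader's default.
#'
#' @param panel a `genotype_panel`.
#' @param prefix output path prefix.
#' @param format "bed" or "ped".
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix, format = c("bed", "ped")) {
  format <- match.arg(format)
  map <- panel$map
  n <- n_animals(panel)
  m <- n_snps(panel)
  fam <- data.frame(fid = panel$animal_ids, iid = panel$animal_ids,
                    pat = 0L, mat = 0L, sex = 0L, pheno = -9L)
  if (format == "bed") {
    utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = " ",
                       row.names = FALSE, col.names = FALSE)
    bim <- data.frame(chr = map$chr, snp = map$snp_id, cm = 0, pos = map$pos,
                      a1 = map$a2, a2 = map$a1) # allele 1 = counted allele
    utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    ## 2-bit codes per genotype, SNP-major: 0 = hom allele1, 1 = missing,
    ## 2 = het, 3 = hom allele2. Dosage counts allele 1 here.
    code <- matrix(3L, n, m) # dosage 0 -> hom allele2
    d <- panel$dosages
    code[is.na(d)] <- 1L
    code[!is.na(d) & d == 1L] <- 2L
    code[!is.na(d) & d == 2L] <- 0L
    bytes_per_snp <- ceiling(n / 4)
    pad <- 4L * bytes_per_snp - n
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con), add = TRUE)
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    mult <- c(1L, 4L, 16L, 64L)
    for (j in seq_len(m)) {
      cj <- c(code[, j], integer(pad))
      quads <- matrix(cj, nrow = 4L)
      writeBin(as.raw(colSums(quads * mult)), con)
    }
  } else {
    mp <- data.frame(chr = map$chr, snp = map$snp_id, cm = 0, pos = map$pos)
    utils::write.table(mp, paste0(prefix, ".map"), quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    d <- panel$dosages
    a2 <- map$a2; a1 <- map$a1
    lines <- vapply(seq_len(n), function(i) {
      g <- d[i, ]
      al1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, a2, a1))
      al2 <- ifelse(is.na(g), "0", ifelse(g == 2L, a2, a1))
      paste(c(fam$fid[i], fam$iid[i], 0, 0, 0, -9,
              as.vector(rbind(al1, al2))), collapse = " ")
    }, character(1))
    writeLines(lines, paste0(prefix, ".ped"))
  }
  invisible(prefix)
}

#' Read genotypes in PLINK format
#'
#' Auto-detects `.bed`/`.bim`/`.fam` (binary) or `.ped`/`.map` (text) at
#' `prefix`. By default the `.bim` allele-1 is treated as the counted (A2)
#' allele, so dosages are counts of allele 1; set `count_allele1 = FALSE`
#' for the opposite convention (dialects differ). Missing genotypes map to
#' `NA`, never to 0.
#'
#' @param prefix path prefix.
#' @param count_allele1 count `.bim` allele 1 as A2 (default TRUE).
#' @return a `genotype_panel` (LD mask unset).
#' @export
read_plink <- function(prefix, count_allele1 = TRUE) {
  if (file.exists(paste0(prefix, ".bed"))) {
    .read_bed(prefix, count_allele1)
  } else if (file.exists(paste0(prefix, ".ped"))) {
    .read_ped(prefix)
  } else {
    stop_config("no .bed or .ped file found at prefix '%s'", prefix)
  }
}

.read_bed <- function(prefix, count_allele1) {
  fam <- utils::read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  bim <- utils::read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE)
  names(bim) <- c("chr", "snp_id", "cm", "pos", "al1", "al2")
  ids <- as.character(fam[[2]])
  if (anyDuplicated(ids)) stop_config("%s.fam: duplicated animal ids", prefix)
  n <- length(ids); m <- nrow(bim)
  bytes_per_snp <- as.integer(ceiling(n / 4))
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3L + as.double(bytes_per_snp) * m + 1L)
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop_config("%s.bed: bad magic bytes", prefix)
  }
  if (raw[3] != as.raw(0x01)) stop_config("%s.bed: not SNP-major", prefix)
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_snp * m) {
    stop_config("%s.bed: expected %d data bytes, found %d", prefix,
                bytes_per_snp * m, length(body))
  }
  ## decode all four 2-bit fields of every byte value once
  lut <- sapply(0:3, function(k) bitwAnd(bitwShiftR(0:255, 2L * k), 3L))
  codes <- lut[as.integer(body) + 1L, ] # (bytes) x 4, row-major over snp bytes
  codes <- matrix(t(codes), nrow = 4L * bytes_per_snp) # per-SNP columns
  codes <- codes[seq_len(n), , drop = FALSE]
  ## code -> dosage of allele1: 0 -> 2, 2 -> 1, 3 -> 0, 1 -> NA
  dmap <- c(2L, NA_integer_, 1L, 0L)
  dos <- matrix(dmap[codes + 1L], nrow = n)
  if (!count_allele1) dos <- 2L - dos
  a2 <- if (count_allele1) bim$al1 else bim$al2
  a1 <- if (count_allele1) bim$al2 else bim$al1
  map <- data.frame(snp_id = as.character(bim$snp_id), chr = bim$chr,
                    pos = bim$pos, a1 = a1, a2 = a2,
                    stringsAsFactors = FALSE)
  new_genotype_panel(dos, map, animal_ids = ids)
}

.read_ped <- function(prefix) {
  mp <- utils::read.table(paste0(prefix, ".map"), stringsAsFactors = FALSE)
  names(mp) <- c("chr", "snp_id", "cm", "pos")
  lines <- readLines(paste0(prefix, ".ped"))
  lines <- lines[nzchar(trimws(lines))]
  m <- nrow(mp)
  n <- length(lines)
  dos <- matrix(NA_integer_, n, m)
  ids <- character(n)
  a_ref <- rep(NA_character_, m) # counted allele per SNP: first non-missing seen
  a_alt <- rep(NA_character_, m)
  gmat <- matrix(NA_character_, n, 2L * m)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * m) {
      stop_config("%s.ped: line %d has %d fields, expected %d", prefix, i,
                  length(f), 6L + 2L * m)
    }
    ids[i] <- f[2]
    gmat[i, ] <- f[-(1:6)]
  }
  if (anyDuplicated(ids)) stop_config("%s.ped: duplicated animal ids", prefix)
  for (j in seq_len(m)) {
    al <- gmat[, c(2L * j - 1L, 2L * j), drop = FALSE]
    obs <- al[al != "0"]
    u <- unique(obs)
    if (length(u) > 2L) stop_config("%s.ped: SNP %d has >2 alleles", prefix, j)
    ## text .ped carries no allele order; count the lexicographically last
    ## label (deterministic, and the writer's counted allele sorts last)
    a_ref[j] <- if (length(u)) max(u) else "A"
    a_alt[j] <- if (length(u) > 1L) min(u) else a_ref[j]
    miss <- al[, 1] == "0" | al[, 2] == "0"
    dos[!miss, j] <- (al[!miss, 1] == a_ref[j]) + (al[!miss, 2] == a_ref[j])
  }
  map <- data.frame(snp_id = as.character(mp$snp_id), chr = mp$chr,
                    pos = mp$pos, a1 = a_alt, a2 = a_ref,
                    stringsAsFactors = FALSE)
  new_genotype_panel(dos, map, animal_ids = ids)
}
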