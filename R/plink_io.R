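#' Read a PLINK v1 binary fileset
#'
#' Reads `prefix.bed`, `prefix.bim`, `prefix.fam` into a
#' [genotype_dataset()]. Only SNP-major .bed files (magic bytes
#' `0x6C 0x1B`, mode byte `0x01`) are supported. Genotype values count
#' copies of the .bim A1 allele; the two-bit missing code maps to `NA`.
#' .fam phenotype 1 is control, 2 is case, anything else missing.
#'
#' @param prefix path stem of the fileset (no extension).
#' @param build optional assembly label stored as marker metadata.
#' @return A [genotype_dataset()] with markers sorted by (chrom, bp).
#' @export
read_plink <- function(prefix, build = NA_character_) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing_f <- paths[!file.exists(paths)]
  if (length(missing_f))
    stop("missing PLINK file(s): ", paste(missing_f, collapse = ", "))
  bim <- if (file.size(paths[2]) == 0) {
    data.frame(chrom = character(0), id = character(0), cm = numeric(0),
               bp = integer(0), a1 = character(0), a2 = character(0))
  } else {
    utils::read.table(paths[2], header = FALSE, sep = "",
                      colClasses = c("character", "character", "numeric",
                                     "integer", "character", "character"),
                      col.names = c("chrom", "id", "cm", "bp", "a1", "a2"))
  }
  fam <- utils::read.table(paths[3], header = FALSE, sep = "",
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "integer"),
                           col.names = c("fid", "iid", "pat", "mat",
                                         "sex", "pheno"))
  m <- nrow(bim); n <- nrow(fam)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes): ", paths[1])
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported (mode byte 0x01)")
  bpm <- ceiling(n / 4)                      # bytes per marker
  if (length(raw) - 3L != bpm * m)
    stop("dimension mismatch: .bed payload is ", length(raw) - 3L,
         " bytes, expected ", bpm * m, " for ", n, " samples x ",
         m, " markers")
  calls <- if (m == 0L || n == 0L) {
    matrix(integer(0), nrow = n, ncol = m)
  } else {
    codes <- plink_decode_table()             # 256 x 4
    v <- as.integer(raw[-(1:3)])
    decoded <- array(t(codes[v + 1L, , drop = FALSE]), dim = c(4L * bpm, m))
    decoded[seq_len(n), , drop = FALSE]
  }
  markers <- data.frame(id = bim$id, chrom = bim$chrom, bp = bim$bp,
                        allele_counted = bim$a1, allele_other = bim$a2,
                        build = rep(build, nrow(bim)),
                        stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = fam$iid,
    phenotype = ifelse(fam$pheno == 2L, "case",
                       ifelse(fam$pheno == 1L, "control", NA_character_)),
    sex = ifelse(fam$sex == 1L, "M", ifelse(fam$sex == 2L, "F", NA_character_)),
    age = NA_real_, stringsAsFactors = FALSE)
  genotype_dataset(markers, samples, calls)
}

# 2-bit genotype codes, 4 samples per byte, least-significant pair first:
# 00 -> 2 copies of A1, 01 -> missing, 10 -> 1 copy, 11 -> 0 copies
plink_decode_table <- function() {
  map <- c(2L, NA_integer_, 1L, 0L)
  b <- 0:255
  cbind(map[bitwAnd(b, 3L) + 1L],
        map[bitwAnd(bitwShiftR(b, 2L), 3L) + 1L],
        map[bitwAnd(bitwShiftR(b, 4L), 3L) + 1L],
        map[bitwAnd(bitwShiftR(b, 6L), 3L) + 1L])
}

#' Write a PLINK v1 binary fileset
#'
#' Bit-exact SNP-major PLINK v1 encoding; `read_plink(write_plink(d))`
#' recovers `d` (age is not representable in .fam and is written as
#' missing). Missing phenotype is written as -9, missing sex as 0.
#'
#' @param dataset a [genotype_dataset()].
#' @param prefix output path stem.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(dataset, prefix) {
  m <- nrow(dataset$markers); n <- nrow(dataset$samples)
  bim <- data.frame(dataset$markers$chrom, dataset$markers$id, rep(0L, m),
                    dataset$markers$bp, dataset$markers$allele_counted,
                    dataset$markers$allele_other)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  ph <- ifelse(is.na(dataset$samples$phenotype), -9L,
               ifelse(dataset$samples$phenotype == "case", 2L, 1L))
  sx <- ifelse(is.na(dataset$samples$sex), 0L,
               ifelse(dataset$samples$sex == "M", 1L, 2L))
  fam <- data.frame(dataset$samples$sample_id, dataset$samples$sample_id,
                    rep(0L, n), rep(0L, n), sx, ph)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  if (m > 0L && n > 0L) {
    # genotype -> 2-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
    code <- matrix(3L, nrow = 4L * ceiling(n / 4), ncol = m)
    g <- dataset$calls
    cd <- ifelse(is.na(g), 1L, c(3L, 2L, 0L)[g + 1L])
    code[seq_len(n), ] <- cd
    code[seq.int(n + 1L, length.out = nrow(code) - n), ] <- 0L  # pad bits 00
    i <- seq(1, nrow(code), by = 4)
    bytes <- code[i, , drop = FALSE] + 4L * code[i + 1L, , drop = FALSE] +
      16L * code[i + 2L, , drop = FALSE] + 64L * code[i + 3L, , drop = FALSE]
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}
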