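#' Read and write plot imagery and tabular intermediates
#'
#' Plot imagery is serialized in plain-text formats so that every intermediate
#' is inspectable and diffable: RGB images as ASCII NetPBM `P3` (PPM), binary
#' masks as ASCII `P2` (PGM, values 0/255), and DSM rasters as a small
#' self-describing text grid (`nrow ncol` header followed by one row of
#' height values in meters per line). Traits, genotype scores, and metrics are
#' CSV; manifests are JSON.
#'
#' @param img for `write_ppm`, an `H x W x 3` integer-like array in \[0, 255\].
#' @param path file path.
#' @name plot_io
NULL

#' @rdname plot_io
#' @export
write_ppm <- function(img, path) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- aperm(img, c(3, 2, 1)) # interleave R,G,B per pixel, row-major raster
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), "255"), con)
  writeLines(paste(as.integer(px), collapse = " "), con)
  invisible(path)
}

#' @rdname plot_io
#' @export
read_ppm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  stopifnot(toks[1] == "P3")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.integer(toks[-(1:4)])
  stopifnot(length(vals) == 3 * w * h)
  aperm(array(vals, dim = c(3, w, h)), c(3, 2, 1))
}

#' @rdname plot_io
#' @param mask an `H x W` 0/1 (or logical) matrix.
#' @export
write_pgm <- function(mask, path) {
  h <- nrow(mask); w <- ncol(mask)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(w, h), "255"), con)
  writeLines(paste(as.integer(t(mask) > 0) * 255L, collapse = " "), con)
  invisible(path)
}

#' @rdname plot_io
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  stopifnot(toks[1] == "P2")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.integer(toks[-(1:4)])
  matrix(vals > 0, nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname plot_io
#' @param dsm an `H x W` numeric matrix of heights (meters).
#' @export
write_dsm <- function(dsm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(dsm), ncol(dsm)), con)
  writeLines(apply(dsm, 1, function(r) paste(format(r, digits = 9), collapse = " ")), con)
  invisible(path)
}

#' @rdname plot_io
#' @export
read_dsm <- function(path) {
  toks <- scan(path, what = numeric(), quiet = TRUE)
  h <- as.integer(toks[1]); w <- as.integer(toks[2])
  matrix(toks[-(1:2)], nrow = h, ncol = w, byrow = TRUE)
}

#' Write or read a genotype score matrix
#'
#' The score-matrix CSV has accessions as rows (first column `accession`),
#' SNPs as columns, entries in \{-1, 0, 1\} or empty for missing. A minimal
#' biallelic VCF route (`GT` field only, haploid-coded diploid genotypes
#' `0/0`, `0/1`, `1/1`, `./.`) is provided for interoperability with standard
#' tooling.
#'
#' @param geno a `genotype_matrix` (see [simulate_genotypes()]).
#' @param path output path.
#' @name genotype_io
NULL

#' @rdname genotype_io
#' @export
write_genotypes_csv <- function(geno, path) {
  df <- data.frame(accession = geno$accession_ids, geno$scores,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname genotype_io
#' @export
read_genotypes_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  scores <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(scores) <- "double"
  rownames(scores) <- df$accession
  new_genotype_matrix(scores, df$accession, colnames(scores))
}

#' @rdname genotype_io
#' @export
write_genotypes_vcf <- function(geno, path) {
  gt_code <- function(s) {
    out <- rep("./.", length(s))
    out[!is.na(s) & s == -1] <- "0/0"
    out[!is.na(s) & s == 0] <- "0/1"
    out[!is.na(s) & s == 1] <- "1/1"
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=lspheno synthetic genotypes",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$accession_ids), collapse = "\t")),
             con)
  n_snp <- ncol(geno$scores)
  for (k in seq_len(n_snp)) {
    rec <- c("1", as.character(k), geno$snp_ids[k], "A", "T", ".", "PASS", ".",
             "GT", gt_code(geno$scores[, k]))
    writeLines(paste(rec, collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname genotype_io
#' @export
read_genotypes_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(body[1], "\t")[[1]]
  acc <- hdr[-(1:9)]
  recs <- strsplit(body[-1], "\t")
  snp_ids <- vapply(recs, `[`, "", 3)
  scores <- matrix(NA_real_, nrow = length(acc), ncol = length(recs),
                   dimnames = list(acc, snp_ids))
  map <- c("0/0" = -1, "0/1" = 0, "1/0" = 0, "1/1" = 1)
  for (k in seq_along(recs)) {
    gt <- sub(":.*", "", recs[[k]][-(1:9)])
    scores[, k] <- unname(map[gt])
  }
  new_genotype_matrix(scores, acc, snp_ids)
}

# Write an object as pretty JSON (manifests, configs, summaries).
write_manifest <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

read_manifest <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
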