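#' Read a long-format phenotype table
#'
#' Expects columns `cultivar`, `season`, `rep`, `subgroup`, `trait`,
#' `value` (a `year_of_release` column is optional). Malformed rows and
#' duplicate plot keys are rejected with the offending line/key named
#' rather than silently coerced.
#'
#' @param path CSV file path.
#' @return a `phenotype_table` `data.frame`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop_sg("file not found: %s", path)
  dat <- read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("cultivar", "season", "rep", "subgroup", "trait", "value")
  missing_cols <- setdiff(need, names(dat))
  if (length(missing_cols) > 0L) {
    stop_sg("missing required column(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  suppressWarnings(val <- as.numeric(dat$value))
  bad <- which(is.na(val) & !is.na(dat$value) & dat$value != "")
  if (length(bad) > 0L) {
    stop_sg("non-numeric value(s) at data line(s) %s",
            paste(head(bad, 5), collapse = ", "))
  }
  dat$value <- val
  for (col in c("cultivar", "season", "rep", "subgroup", "trait")) {
    dat[[col]] <- as.character(dat[[col]])
  }
  key <- paste(dat$cultivar, dat$season, dat$rep, dat$trait, sep = "/")
  dup <- duplicated(key)
  if (any(dup)) {
    stop_sg("duplicate plot row(s), first offending key: %s",
            key[which(dup)[1]])
  }
  class(dat) <- c("phenotype_table", "data.frame")
  dat
}

#' Write a phenotype table
#' @param table a phenotype table.
#' @param path output CSV path.
#' @export
write_phenotypes <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a daily weather table
#'
#' Requires a `date` column (ISO-8601) and either `tmean` or both
#' `tmin`/`tmax`.
#'
#' @param path CSV file path.
#' @return `data.frame` with parsed dates.
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) stop_sg("file not found: %s", path)
  dat <- read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  if (!"date" %in% names(dat)) stop_sg("weather needs a `date` column")
  d <- as.Date(dat$date, format = "%Y-%m-%d")
  if (anyNA(d)) {
    stop_sg("unparseable date at data line(s) %s",
            paste(head(which(is.na(d)), 5), collapse = ", "))
  }
  dat$date <- d
  if (!("tmean" %in% names(dat) ||
        all(c("tmin", "tmax") %in% names(dat)))) {
    stop_sg("weather needs `tmean` or both `tmin` and `tmax`")
  }
  dat
}

#' Write a weather table
#' @param weather `data.frame` with `date` and temperature columns.
#' @param path output CSV path.
#' @export
write_weather <- function(weather, path) {
  weather$date <- format(as.Date(weather$date), "%Y-%m-%d")
  write.csv(weather, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a BLUE table
#' @param path CSV file path.
#' @return a `blue_table` `data.frame`.
#' @export
read_blues <- function(path) {
  if (!file.exists(path)) stop_sg("file not found: %s", path)
  dat <- read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("cultivar", "trait", "estimate")
  if (!all(need %in% names(dat))) {
    stop_sg("BLUE table needs columns %s", paste(need, collapse = ", "))
  }
  if ("season" %in% names(dat)) {
    dat$season[dat$season == ""] <- NA_character_
    dat$season <- as.character(dat$season)
  }
  key <- paste(dat$cultivar, dat$trait,
               if ("season" %in% names(dat)) dat$season else "", sep = "/")
  if (anyDuplicated(key)) {
    stop_sg("duplicate BLUE row: %s", key[which(duplicated(key))[1]])
  }
  class(dat) <- c("blue_table", "data.frame")
  dat
}

#' @rdname read_blues
#' @param blues a `blue_table`.
#' @export
write_blues <- function(blues, path) {
  write.csv(as.data.frame(blues), path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}

#' Read genotypes from a tab-delimited dosage matrix plus marker map
#'
#' The dosage file has markers in rows (first column `marker`), cultivars
#' in columns, entries 0/1/2 with empty or NA for missing. The map CSV has
#' columns `marker`, `chrom`, `pos_mbp`.
#'
#' @param geno_path tab-delimited dosage file.
#' @param map_path marker map CSV.
#' @return a [geno_matrix()].
#' @export
read_genotypes <- function(geno_path, map_path) {
  for (p in c(geno_path, map_path)) {
    if (!file.exists(p)) stop_sg("file not found: %s", p)
  }
  dat <- read.delim(geno_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(dat)[1] != "marker") {
    stop_sg("first column of the genotype file must be `marker`")
  }
  m <- as.matrix(dat[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- dat$marker
  map <- read.csv(map_path, stringsAsFactors = FALSE, strip.white = TRUE)
  geno_matrix(m, map)
}

#' @rdname read_genotypes
#' @param g a [geno_matrix()].
#' @export
write_genotypes <- function(g, geno_path, map_path) {
  stopifnot(inherits(g, "geno_matrix"))
  out <- data.frame(marker = rownames(g$dosage), g$dosage,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, geno_path, sep = "\t", row.names = FALSE, quote = FALSE,
              na = "")
  write.csv(g$map, map_path, row.names = FALSE, quote = FALSE)
  invisible(geno_path)
}

#' Write genotypes as a minimal VCF (GT field, biallelic sites)
#'
#' Dosage 0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`, missing -> `./.`; positions
#' are converted from Mbp to bp at the boundary. Placeholder REF/ALT
#' alleles A/B are used since the simulator does not track nucleotides.
#'
#' @param g a [geno_matrix()].
#' @param path output `.vcf` path (uncompressed).
#' @export
write_genotypes_vcf <- function(g, path) {
  stopifnot(inherits(g, "geno_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=staygreen",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(g$dosage)),
                     collapse = "\t")), con)
  gt <- matrix(c("0/0", "0/1", "1/1")[g$dosage + 1L], nrow = nrow(g$dosage))
  gt[is.na(g$dosage)] <- "./."
  pos_bp <- as.integer(round(g$map$pos_mbp * 1e6))
  lines <- paste(g$map$chrom, pos_bp, g$map$marker, "A", "B", ".", "PASS",
                 ".", "GT", apply(gt, 1, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read genotypes from a VCF (GT field, biallelic records)
#'
#' Uses VariantAnnotation when available. ALT-allele dosages are derived
#' from the GT field; positions are reported in Mbp.
#'
#' @param path VCF path.
#' @return a [geno_matrix()].
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop_sg("reading VCF requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  dos[gt %in% c("1/1", "1|1")] <- 2
  rr <- SummarizedExperiment::rowRanges(vcf)
  map <- data.frame(marker = rownames(gt),
                    chrom = as.character(GenomicRanges::seqnames(rr)),
                    pos_mbp = GenomicRanges::start(rr) / 1e6,
                    stringsAsFactors = FALSE)
  geno_matrix(dos, map)
}

#' Write an association-scan result table
#' @param res an `association_result`.
#' @param path output CSV path.
#' @export
write_association <- function(res, path) {
  write.csv(as.data.frame(res), path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}

#' Read a pipeline configuration (JSON)
#' @param path JSON config path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_sg("config not found: %s", path)
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}
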