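#' Construct a genotype panel
#'
#' A genotype panel holds a sample-by-variant dosage matrix (allele counts of
#' the counted allele `a1`, in `[0, 2]`, `NA` = missing) together with variant
#' metadata and optional per-sample ancestry labels. It is the substrate for
#' PGI scoring, PCA and LD computation throughout the package.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns.
#' @param variants data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `a1` (counted allele), `a2`.
#' @param samples character vector of sample ids (defaults to rownames).
#' @param ancestry optional character vector of per-sample ancestry labels.
#' @param validate check dosage range and metadata consistency (default
#'   `TRUE`; internal callers that construct known-good panels skip it).
#' @return an object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, variants, samples = rownames(dosages),
                           ancestry = NULL, validate = TRUE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("id", "chrom", "pos", "a1", "a2")
  if (!all(req %in% names(variants)))
    stop("variants must have columns: ", paste(req, collapse = ", "))
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosages)))
  samples <- as.character(samples)
  if (nrow(dosages) != length(samples))
    stop("dosage rows (", nrow(dosages), ") != number of samples (",
         length(samples), ")")
  if (ncol(dosages) != nrow(variants))
    stop("dosage columns (", ncol(dosages), ") != number of variants (",
         nrow(variants), ")")
  if (validate) {
    if (anyDuplicated(variants$id))
      stop("variant ids must be unique within a panel")
    if (any(variants$pos < 1)) stop("positions must be >= 1 (1-based)")
    if (!all(nzchar(variants$a1)) || !all(nzchar(variants$a2)))
      stop("allele strings must be non-empty")
    rng <- suppressWarnings(range(dosages, na.rm = TRUE))
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
      stop("non-missing dosages must lie in [0, 2]")
  }
  if (!is.null(ancestry)) {
    ancestry <- as.character(ancestry)
    if (length(ancestry) != length(samples))
      stop("ancestry labels must match number of samples")
  }
  dimnames(dosages) <- list(samples, variants$id)
  structure(list(samples = samples, variants = variants,
                 dosages = dosages, ancestry = ancestry),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$samples), "samples x",
      nrow(x$variants), "variants\n")
  if (!is.null(x$ancestry)) {
    tab <- table(x$ancestry)
    cat("ancestry:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  nmiss <- sum(is.na(x$dosages))
  if (nmiss > 0) cat("missing dosages:", nmiss, "\n")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

#' Subset a genotype panel by samples and/or variants
#'
#' @param panel a `genotype_panel`.
#' @param samples character ids or logical/integer index over samples.
#' @param variants character ids or logical/integer index over variants.
#' @return a `genotype_panel`.
#' @export
subset_panel <- function(panel, samples = NULL, variants = NULL) {
  si <- seq_along(panel$samples)
  vi <- seq_len(nrow(panel$variants))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, panel$samples) else si[samples]
    if (anyNA(si)) stop("unknown sample id(s)")
  }
  if (!is.null(variants)) {
    vi <- if (is.character(variants)) match(variants, panel$variants$id) else vi[variants]
    if (anyNA(vi)) stop("unknown variant id(s)")
  }
  genotype_panel(panel$dosages[si, vi, drop = FALSE],
                 panel$variants[vi, , drop = FALSE],
                 samples = panel$samples[si],
                 ancestry = if (!is.null(panel$ancestry)) panel$ancestry[si],
                 validate = FALSE)
}

#' Read genotypes from PLINK 1.9 bed/bim/fam or VCF
#'
#' For PLINK input, `path` is the fileset prefix (or the `.bed` path); the A1
#' allele of the `.bim` file is the counted allele. For VCF input the counted
#' allele is the first ALT allele; multi-allelic records are rejected. Only
#' hard-call GT genotypes are read from VCF.
#'
#' @param path file path (PLINK prefix or VCF file).
#' @param format `"plink-bed"` or `"vcf"`.
#' @return a [genotype_panel()].
#' @export
read_genotypes <- function(path, format = c("plink-bed", "vcf")) {
  format <- match.arg(format)
  if (format == "plink-bed") read_plink(path) else read_vcf_panel(path)
}

read_vcf_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    stop("multi-allelic VCF record(s) not supported: ",
         paste(utils::head(fix[multi, "ID"], 5), collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, names(gt)))
  # dosage of the ALT allele from GT strings ("0/1", "1|1", "./.")
  count_alt <- function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    if (!all(al %in% c("0", "1")))
      stop("unexpected GT allele code '", g, "' (biallelic GT expected)")
    sum(al == "1")
  }
  dos <- apply(gt, c(1, 2), count_alt)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  variants <- data.frame(id = ids, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         a1 = alt, a2 = fix[, "REF"],
                         stringsAsFactors = FALSE)
  genotype_panel(t(dos), variants, samples = colnames(gt))
}

plink_prefix <- function(path) sub("\\.bed$", "", path)

read_plink <- function(path) {
  pre <- plink_prefix(path)
  bed <- paste0(pre, ".bed"); bim <- paste0(pre, ".bim"); fam <- paste0(pre, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("file not found: ", f)
  bimdf <- utils::read.table(bim, stringsAsFactors = FALSE,
                             col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
                             colClasses = c("character", "character", "numeric",
                                            "integer", "character", "character"))
  famdf <- utils::read.table(fam, stringsAsFactors = FALSE)
  if (ncol(famdf) < 2) stop("malformed .fam file: ", fam)
  samples <- as.character(famdf[[2]])
  n <- length(samples); m <- nrow(bimdf)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("malformed .bed file (bad magic number): ", bed)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported: ", bed)
  bpv <- ceiling(n / 4)
  if (length(raw) - 3L != bpv * m)
    stop("malformed .bed file: expected ", bpv * m, " genotype bytes, found ",
         length(raw) - 3L)
  body <- as.integer(raw[-(1:3)])
  # unpack 2-bit codes, sample-fastest within variant
  codes <- matrix(0L, nrow = 4 * bpv, ncol = m)
  b <- matrix(body, nrow = bpv)
  codes[seq(1, 4 * bpv, by = 4), ] <- b %% 4L
  codes[seq(2, 4 * bpv, by = 4), ] <- (b %/% 4L) %% 4L
  codes[seq(3, 4 * bpv, by = 4), ] <- (b %/% 16L) %% 4L
  codes[seq(4, 4 * bpv, by = 4), ] <- (b %/% 64L) %% 4L
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00 -> 2 copies of A1, 10 -> 1, 11 -> 0, 01 -> missing
  dos <- matrix(NA_real_, n, m)
  dos[codes == 0L] <- 2; dos[codes == 2L] <- 1; dos[codes == 3L] <- 0
  variants <- data.frame(id = bimdf$id, chrom = bimdf$chrom, pos = bimdf$pos,
                         a1 = bimdf$a1, a2 = bimdf$a2, stringsAsFactors = FALSE)
  genotype_panel(dos, variants, samples = samples)
}

#' Write a genotype panel as PLINK 1.9 bed/bim/fam
#'
#' Dosages are rounded to hard calls; `NA` becomes the PLINK missing code.
#'
#' @param panel a `genotype_panel`.
#' @param prefix output fileset prefix.
#' @return the prefix, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  n <- length(panel$samples); m <- nrow(panel$variants)
  v <- panel$variants
  utils::write.table(data.frame(v$chrom, v$id, 0, v$pos, v$a1, v$a2),
                     paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(panel$samples, panel$samples, 0, 0, 0, -9),
                     paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  hard <- round(panel$dosages)
  codes <- matrix(1L, n, m)            # 01 = missing
  codes[!is.na(hard) & hard == 2] <- 0L
  codes[!is.na(hard) & hard == 1] <- 2L
  codes[!is.na(hard) & hard == 0] <- 3L
  bpv <- ceiling(n / 4)
  pad <- matrix(0L, 4 * bpv - n, m)
  cc <- rbind(codes, pad)
  i1 <- seq(1, 4 * bpv, by = 4)
  bytes <- cc[i1, , drop = FALSE] + 4L * cc[i1 + 1, , drop = FALSE] +
    16L * cc[i1 + 2, , drop = FALSE] + 64L * cc[i1 + 3, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

#' Write a genotype panel as a minimal VCF 4.2 file (hard calls)
#'
#' @param panel a `genotype_panel`. The counted allele `a1` is written as ALT.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_vcf <- function(panel, path) {
  hard <- round(panel$dosages)
  gt <- matrix("./.", nrow(hard), ncol(hard))
  gt[!is.na(hard) & hard == 0] <- "0/0"
  gt[!is.na(hard) & hard == 1] <- "0/1"
  gt[!is.na(hard) & hard == 2] <- "1/1"
  v <- panel$variants
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", panel$samples), collapse = "\t"))
  rows <- vapply(seq_len(nrow(v)), function(j) {
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$a2[j], v$a1[j], ".", "PASS", ".",
            "GT", gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, rows), path)
  invisible(path)
}

#' Write any tabular result as tab-delimited UTF-8 text
#'
#' @param records a data.frame (possibly empty; the header is still written).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_table <- function(records, path) {
  records <- as.data.frame(records)
  ok <- tryCatch({
    data.table::fwrite(records, path, sep = "\t", quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) stop("cannot write to '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read a tab-delimited table written by [write_table()]
#' @param path file path.
#' @return a data.frame.
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

flip_strand <- function(a) {
  out <- COMPLEMENT[a]
  out[is.na(out)] <- a[is.na(out)]   # non-ACGT alleles pass through
  unname(out)
}

is_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Align a weight or summary-statistics table to a genotype panel
#'
#' Matches variants by id and reconciles the effect allele with the panel's
#' counted allele. Where the effect allele equals the panel's other allele the
#' sign of `weight`/`beta` is flipped and `eaf` (if present) replaced by
#' `1 - eaf`. Alleles are also compared after strand complementation.
#' Strand-ambiguous variants (A/T, C/G) are dropped by default because the
#' two strand interpretations cannot be distinguished.
#'
#' @param tbl data.frame with `id`, `effect_allele`, `other_allele` and at
#'   least one of `weight`, `beta`; optionally `eaf`.
#' @param panel a `genotype_panel`.
#' @param drop_ambiguous drop A/T and C/G variants (default `TRUE`).
#' @return the aligned table, with an `"alignment"` attribute holding the
#'   report (counts of matched / sign-flipped / strand-flipped / dropped).
#' @export
align_alleles <- function(tbl, panel, drop_ambiguous = TRUE) {
  tbl <- as.data.frame(tbl, stringsAsFactors = FALSE)
  req <- c("id", "effect_allele", "other_allele")
  if (!all(req %in% names(tbl)))
    stop("table must have columns: ", paste(req, collapse = ", "))
  valcols <- intersect(c("weight", "beta"), names(tbl))
  if (length(valcols) == 0) stop("table must have a 'weight' or 'beta' column")
  idx <- match(tbl$id, panel$variants$id)
  matched <- !is.na(idx)
  n_unmatched <- sum(!matched)
  out <- tbl[matched, , drop = FALSE]
  pv <- panel$variants[idx[matched], , drop = FALSE]
  ea <- toupper(out$effect_allele); oa <- toupper(out$other_allele)
  a1 <- toupper(pv$a1); a2 <- toupper(pv$a2)
  amb <- is_ambiguous(ea, oa)
  same  <- ea == a1 & oa == a2
  swap  <- ea == a2 & oa == a1
  csame <- !amb & !same & !swap & flip_strand(ea) == a1 & flip_strand(oa) == a2
  cswap <- !amb & !same & !swap & flip_strand(ea) == a2 & flip_strand(oa) == a1
  keep <- (same | swap | csame | cswap) & !(amb & drop_ambiguous)
  flip <- (swap | cswap) & keep
  strandflip <- (csame | cswap) & keep
  n_amb <- sum(amb & (same | swap) & drop_ambiguous)
  n_irrec <- sum(!keep) - n_amb
  out <- out[keep, , drop = FALSE]
  pvk <- pv[keep, , drop = FALSE]
  fl <- flip[keep]; sf <- strandflip[keep]
  for (vc in valcols) out[[vc]][fl] <- -out[[vc]][fl]
  if ("eaf" %in% names(out)) out$eaf[fl] <- 1 - out$eaf[fl]
  # rewrite alleles in the panel's coding so re-alignment is a no-op
  out$effect_allele <- pvk$a1
  out$other_allele <- pvk$a2
  if (nrow(out) == 0)
    stop("zero variants could be aligned between the table and the panel")
  rownames(out) <- NULL
  attr(out, "alignment") <- list(
    n_input = nrow(tbl), n_matched = nrow(out), n_unmatched = n_unmatched,
    n_sign_flipped = sum(fl), n_strand_flipped = sum(sf),
    n_ambiguous_dropped = n_amb, n_irreconcilable = n_irrec)
  out
}
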