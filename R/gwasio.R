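#' Construct a summary-statistics object
#'
#' Wraps a per-variant association table for one trait. Records are
#' normalized on construction: alleles are uppercased and the table is
#' sorted by (chrom, pos).
#'
#' @param snps Data frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf` (may be NA), `beta`, `se`, `p`,
#'   `n`.
#' @param trait Trait label.
#' @param cohort Cohort label.
#' @param lambda Genomic-control lambda, if already applied.
#' @return An object of class `sumstats`.
#' @export
sumstats <- function(snps, trait = "trait", cohort = "cohort",
                     lambda = NULL) {
  req <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
           "eaf", "beta", "se", "p", "n")
  missing_cols <- setdiff(req, names(snps))
  if (length(missing_cols) > 0) {
    stop(sprintf("sumstats missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  snps <- snps[req]
  snps$effect_allele <- toupper(snps$effect_allele)
  snps$other_allele <- toupper(snps$other_allele)
  bad_alleles <- !is.na(snps$effect_allele) &
    snps$effect_allele == snps$other_allele
  if (any(bad_alleles)) {
    stop("identical effect and other alleles in sumstats", call. = FALSE)
  }
  if (any(!is.na(snps$se) & snps$se <= 0)) {
    stop("non-positive standard errors in sumstats", call. = FALSE)
  }
  snps <- snps[order(suppressWarnings(as.numeric(snps$chrom)),
                     snps$chrom, snps$pos), , drop = FALSE]
  rownames(snps) <- NULL
  structure(list(snps = snps, trait = trait, cohort = cohort,
                 lambda = lambda),
            class = "sumstats")
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("sumstats: %s (%s), %d variants%s\n", x$trait, x$cohort,
              nrow(x$snps),
              if (!is.null(x$lambda)) sprintf(", lambda = %.4f", x$lambda)
              else ""))
  invisible(x)
}

# Default column-name aliases for summary-statistics dialects.
sumstats_aliases <- function() {
  list(snp_id = c("snp_id", "snp", "rsid", "markername", "variant_id"),
       chrom = c("chrom", "chr", "chromosome"),
       pos = c("pos", "bp", "position", "base_pair_location"),
       effect_allele = c("effect_allele", "a1", "allele1", "ea"),
       other_allele = c("other_allele", "a2", "allele2", "oa", "nea"),
       eaf = c("eaf", "freq", "af", "effect_allele_frequency", "frq"),
       beta = c("beta", "effect", "b"),
       se = c("se", "stderr", "standard_error"),
       p = c("p", "pval", "p_value", "pvalue", "p.value"),
       n = c("n", "samplesize", "n_total"))
}

#' Read GWAS summary statistics from a tab-delimited file
#'
#' Columns are resolved case-insensitively through an alias table covering
#' the common dialects (SNP/rsid/MarkerName, A1/effect_allele, ...); gzip is
#' handled transparently. Rows with unparseable numeric fields are dropped,
#' counted and reported with their line numbers.
#'
#' @param path File path (optionally .gz).
#' @param column_spec Optional named list overriding the alias table; names
#'   are canonical field names, values the column name in the file.
#' @param trait,cohort Labels attached to the result.
#' @return A `sumstats` object with attribute `report` (list: n_read,
#'   n_malformed, malformed_lines).
#' @export
read_sumstats <- function(path, column_spec = NULL,
                          trait = "trait", cohort = "cohort") {
  if (!file.exists(path)) stop_param("file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  hdr <- tolower(names(raw))
  if (anyDuplicated(hdr)) {
    stop(sprintf("duplicated column header in %s", path), call. = FALSE)
  }
  aliases <- sumstats_aliases()
  for (nm in names(column_spec)) aliases[[nm]] <- tolower(column_spec[[nm]])
  idx <- vapply(names(aliases), function(field) {
    hit <- which(hdr %in% aliases[[field]])
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1))
  required <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "p")
  if (any(is.na(idx[required]))) {
    stop(sprintf("required column(s) not resolvable: %s",
                 paste(required[is.na(idx[required])], collapse = ", ")),
         call. = FALSE)
  }
  get_col <- function(field, default = NA) {
    if (is.na(idx[[field]])) rep(default, nrow(raw)) else raw[[idx[[field]]]]
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  df <- data.frame(
    snp_id = get_col("snp_id"),
    chrom = as.character(get_col("chrom", "0")),
    pos = num(get_col("pos", 0)),
    effect_allele = get_col("effect_allele"),
    other_allele = get_col("other_allele"),
    eaf = num(get_col("eaf")),
    beta = num(get_col("beta")),
    se = num(get_col("se")),
    p = num(get_col("p")),
    n = num(get_col("n")),
    stringsAsFactors = FALSE
  )
  # a numeric field that was present in the file but failed to parse marks
  # the row malformed; absent optional fields do not
  present_num <- intersect(c("pos", "eaf", "beta", "se", "p", "n"),
                           names(idx)[!is.na(idx)])
  bad <- rep(FALSE, nrow(df))
  for (field in present_num) {
    bad <- bad | (is.na(df[[field]]) & !is.na(raw[[idx[[field]]]]) &
                    raw[[idx[[field]]]] != "" &
                    tolower(raw[[idx[[field]]]]) != "na")
  }
  bad <- bad | is.na(df$beta) | is.na(df$se) | is.na(df$p)
  ss <- sumstats(df[!bad, , drop = FALSE], trait = trait, cohort = cohort)
  attr(ss, "report") <- list(n_read = nrow(df),
                             n_malformed = sum(bad),
                             malformed_lines = which(bad) + 1L)
  ss
}

#' Write summary statistics to a tab-delimited file
#'
#' @param ss A `sumstats` object.
#' @param path Output path (.gz supported).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  stopifnot(inherits(ss, "sumstats"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(ss$snps, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Quality-control GWAS summary statistics
#'
#' Applies the standard pre-analysis filters: duplicated rsIDs resolved by
#' keeping the record with the lowest p-value; missing per-SNP sample sizes
#' replaced with the published total; missing allele frequencies filled from
#' a reference dataset by rsID with allele alignment (frequency flipped when
#' the effect alleles are swapped); p-values outside (0, 1] removed.
#'
#' @param ss A `sumstats` object.
#' @param reference Optional `sumstats` supplying allele frequencies.
#' @param total_n Published total sample size, used where `n` is missing.
#' @return A `sumstats` object; attribute `report` counts each action.
#' @export
qc_sumstats <- function(ss, reference = NULL, total_n = NULL) {
  stopifnot(inherits(ss, "sumstats"))
  df <- ss$snps
  report <- list(n_in = nrow(df))

  bad_p <- is.na(df$p) | df$p <= 0 | df$p > 1
  report$removed_bad_p <- sum(bad_p)
  df <- df[!bad_p, , drop = FALSE]

  dup <- duplicated(df$snp_id) | duplicated(df$snp_id, fromLast = TRUE)
  report$duplicate_rsids <- length(unique(df$snp_id[dup]))
  if (any(dup)) {
    df <- df[order(df$snp_id, df$p), , drop = FALSE]
    df <- df[!duplicated(df$snp_id), , drop = FALSE]
  }

  miss_n <- is.na(df$n)
  report$n_filled <- sum(miss_n)
  if (any(miss_n)) {
    if (is.null(total_n)) {
      stop("sample sizes missing and no total_n supplied", call. = FALSE)
    }
    df$n[miss_n] <- total_n
  }

  miss_eaf <- is.na(df$eaf)
  report$eaf_filled <- 0L
  if (any(miss_eaf)) {
    if (is.null(reference)) {
      stop("allele frequencies missing and no reference supplied",
           call. = FALSE)
    }
    ref <- reference$snps
    m <- match(df$snp_id[miss_eaf], ref$snp_id)
    fill <- rep(NA_real_, sum(miss_eaf))
    ok <- !is.na(m)
    same <- ok & df$effect_allele[miss_eaf] == ref$effect_allele[m] &
      df$other_allele[miss_eaf] == ref$other_allele[m]
    swap <- ok & df$effect_allele[miss_eaf] == ref$other_allele[m] &
      df$other_allele[miss_eaf] == ref$effect_allele[m]
    fill[same] <- ref$eaf[m[same]]
    fill[swap] <- 1 - ref$eaf[m[swap]]
    df$eaf[miss_eaf] <- fill
    report$eaf_filled <- sum(!is.na(fill))
  }

  out <- sumstats(df, trait = ss$trait, cohort = ss$cohort,
                  lambda = ss$lambda)
  report$n_out <- nrow(out$snps)
  attr(out, "report") <- report
  out
}

#' Apply genomic control to summary statistics
#'
#' The inflation factor lambda is the median of the squared z-statistics
#' divided by the median of a 1-df chi-square (0.4549). When lambda exceeds
#' 1, standard errors are inflated by sqrt(lambda) and p-values recomputed
#' from the corrected z; otherwise the statistics are returned unchanged.
#' Lambda is recorded on the object either way.
#'
#' @param ss A `sumstats` object with at least one variant.
#' @return A `sumstats` object with `lambda` set.
#' @export
genomic_control <- function(ss) {
  stopifnot(inherits(ss, "sumstats"))
  if (nrow(ss$snps) < 1) stop_param("genomic_control needs >= 1 variant")
  z2 <- (ss$snps$beta / ss$snps$se)^2
  lambda <- stats::median(z2) / stats::qchisq(0.5, df = 1)
  df <- ss$snps
  if (lambda > 1) {
    df$se <- df$se * sqrt(lambda)
    df$p <- 2 * stats::pnorm(-abs(df$beta / df$se))
  }
  sumstats(df, trait = ss$trait, cohort = ss$cohort, lambda = lambda)
}

# Align the alleles of `df` to the orientation of (ea, oa) keyed by rsID.
# Returns df with beta/eaf flipped where the alleles were swapped (directly
# or on the complementary strand) and rows with irreconcilable alleles
# dropped; attribute "dropped" lists them.
align_alleles <- function(df, key_snp, key_ea, key_oa) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m <- match(df$snp_id, key_snp)
  ea <- key_ea[m]
  oa <- key_oa[m]
  same <- df$effect_allele == ea & df$other_allele == oa
  swap <- df$effect_allele == oa & df$other_allele == ea
  cea <- unname(comp[df$effect_allele])
  coa <- unname(comp[df$other_allele])
  same_c <- !same & !swap & cea == ea & coa == oa
  swap_c <- !same & !swap & cea == oa & coa == ea
  flip <- swap | swap_c
  keep <- !is.na(m) & (same | swap | same_c | swap_c)
  df$beta[flip] <- -df$beta[flip]
  df$eaf[flip] <- 1 - df$eaf[flip]
  df$effect_allele[keep] <- ea[keep]
  df$other_allele[keep] <- oa[keep]
  out <- df[keep, , drop = FALSE]
  attr(out, "dropped") <- df$snp_id[!keep]
  attr(out, "n_flipped") <- sum(flip & keep)
  out
}

#' Fixed-effect inverse-variance meta-analysis of GWAS cohorts
#'
#' Classical fixed-effect combination: per SNP, beta is the
#' inverse-variance-weighted mean of the cohort betas and the combined
#' standard error is `(sum 1/se_i^2)^(-1/2)`, with the p-value from the
#' normal z. Cohort alleles are harmonized to the first cohort carrying each
#' SNP (sign flips for swapped alleles, strand flips via complement); SNPs
#' with irreconcilable alleles in some cohort lose that cohort's
#' contribution and are reported. The combined sample size is the sum over
#' the cohorts the SNP is present in. With `apply_gc`, genomic control is
#' applied to each cohort first.
#'
#' @param cohorts List of `sumstats` objects.
#' @param apply_gc Apply per-cohort genomic control before combining.
#' @param trait Trait label for the result.
#' @return A `sumstats` object; attribute `report` lists per-cohort lambdas
#'   and dropped SNPs.
#' @export
meta_fixed <- function(cohorts, apply_gc = FALSE, trait = NULL) {
  stopifnot(length(cohorts) >= 1,
            all(vapply(cohorts, inherits, logical(1), "sumstats")))
  lambdas <- NULL
  if (apply_gc) {
    cohorts <- lapply(cohorts, genomic_control)
    lambdas <- vapply(cohorts, function(x) x$lambda, numeric(1))
  }
  # reference orientation: first cohort in which each SNP appears
  all_snps <- unlist(lapply(cohorts, function(x) x$snps$snp_id))
  ref <- do.call(rbind, lapply(cohorts, function(x) {
    x$snps[c("snp_id", "chrom", "pos", "effect_allele", "other_allele")]
  }))
  ref <- ref[!duplicated(ref$snp_id), , drop = FALSE]
  dropped <- character(0)
  aligned <- lapply(cohorts, function(x) {
    a <- align_alleles(x$snps, ref$snp_id, ref$effect_allele,
                       ref$other_allele)
    dropped <<- c(dropped, attr(a, "dropped"))
    a
  })
  tab <- do.call(rbind, aligned)
  w <- 1 / tab$se^2
  num <- tapply(w * tab$beta, tab$snp_id, sum)
  den <- tapply(w, tab$snp_id, sum)
  n_sum <- tapply(tab$n, tab$snp_id, function(x) sum(x, na.rm = TRUE))
  eaf_mean <- tapply(seq_len(nrow(tab)), tab$snp_id, function(i) {
    ok <- !is.na(tab$eaf[i])
    if (!any(ok)) NA_real_
    else sum(tab$eaf[i][ok] * tab$n[i][ok]) / sum(tab$n[i][ok])
  })
  ids <- names(num)
  beta <- as.numeric(num / den)
  se <- as.numeric(1 / sqrt(den))
  m <- match(ids, ref$snp_id)
  out <- sumstats(data.frame(
    snp_id = ids,
    chrom = ref$chrom[m], pos = ref$pos[m],
    effect_allele = ref$effect_allele[m],
    other_allele = ref$other_allele[m],
    eaf = as.numeric(eaf_mean[ids]),
    beta = beta, se = se,
    p = 2 * stats::pnorm(-abs(beta / se)),
    n = as.numeric(n_sum[ids]),
    stringsAsFactors = FALSE
  ), trait = trait %||% cohorts[[1]]$trait, cohort = "meta")
  attr(out, "report") <- list(lambdas = lambdas,
                              dropped_snps = unique(dropped))
  out
}

#' Read an ICD10-to-phecode map
#'
#' Reads the two CSVs of the PheWAS-catalog layout: an ICD10-to-phecode
#' mapping and a phecode definition table (description, category). ICD10
#' codes mapping to multiple phecodes are resolved deterministically by
#' keeping the numerically smallest phecode. Every mapped phecode must have
#' a definition entry.
#'
#' @param icd_map_path CSV with columns `icd10`, `phecode`.
#' @param definitions_path CSV with columns `phecode`, `description`,
#'   `category`.
#' @return A `phecode_map`: list with `icd10` (icd10, phecode) and
#'   `phecodes` (phecode, description, category).
#' @export
read_phecode_map <- function(icd_map_path, definitions_path) {
  icd <- utils::read.csv(icd_map_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  defs <- utils::read.csv(definitions_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(icd) == 0 || !all(c("icd10", "phecode") %in% names(icd))) {
    stop("empty or malformed ICD10 map", call. = FALSE)
  }
  if (nrow(defs) == 0 ||
      !all(c("phecode", "description", "category") %in% names(defs))) {
    stop("empty or malformed phecode definitions", call. = FALSE)
  }
  # multi-mapped ICD10 codes: keep the numerically smallest phecode
  icd <- icd[order(icd$icd10, as.numeric(icd$phecode)), , drop = FALSE]
  icd <- icd[!duplicated(icd$icd10), , drop = FALSE]
  rownames(icd) <- NULL
  undefined <- setdiff(icd$phecode, defs$phecode)
  if (length(undefined) > 0) {
    stop(sprintf("phecode(s) without definition: %s",
                 paste(undefined, collapse = ", ")), call. = FALSE)
  }
  structure(list(icd10 = icd,
                 phecodes = defs[!duplicated(defs$phecode), , drop = FALSE]),
            class = "phecode_map")
}

#' Map ICD10 codes to phecodes
#'
#' @param codes Character vector of ICD10 codes.
#' @param map A `phecode_map`.
#' @return Character vector of phecodes (NA where unmapped).
#' @export
map_icd10 <- function(codes, map) {
  stopifnot(inherits(map, "phecode_map"))
  map$icd10$phecode[match(codes, map$icd10$icd10)]
}
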