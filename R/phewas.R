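#' Define endometriosis case status from ICD10 records
#'
#' A case is any individual carrying an N80.1-N80.9 code. Individuals whose
#' only endometriosis-range code is N80.0 (adenomyosis, a distinct disease)
#' are not cases. The sensitivity cohort is the remainder: females without
#' an endometriosis diagnosis.
#'
#' @param records Data frame with columns `id`, `icd10`.
#' @param ids All individual ids in the cohort (cases are a subset).
#' @return List with logical `case` (named by id) and `sensitivity_ids`.
#' @export
define_endometriosis_cases <- function(records, ids) {
  stopifnot(all(c("id", "icd10") %in% names(records)))
  endo <- grepl("^N80\\.[1-9]", records$icd10)
  case_ids <- unique(records$id[endo])
  case <- stats::setNames(ids %in% case_ids, ids)
  list(case = case, sensitivity_ids = ids[!case])
}

#' Build a phecode case/control indicator table
#'
#' Maps each individual's ICD10 codes to phecodes and keeps phecodes
#' assigned to at least `min_count` participants. Controls for each phecode
#' are all individuals without it (no exclusion-range logic; switchable off
#' is not needed as none is applied).
#'
#' @param records Data frame with columns `id`, `icd10`.
#' @param map A `phecode_map`.
#' @param ids All individual ids in the cohort.
#' @param min_count Minimum number of carriers for inclusion.
#' @return List with `table` (0/1 matrix, individuals x phecodes) and
#'   `phecodes` (data frame: phecode, description, category, n_cases).
#' @export
build_phecode_table <- function(records, map, ids, min_count = 100) {
  stopifnot(inherits(map, "phecode_map"))
  phe <- map_icd10(records$icd10, map)
  keep <- !is.na(phe)
  pairs <- unique(data.frame(id = records$id[keep], phecode = phe[keep],
                             stringsAsFactors = FALSE))
  counts <- table(pairs$phecode)
  included <- names(counts)[counts >= min_count]
  included <- included[order(as.numeric(included))]
  tab <- matrix(0L, nrow = length(ids), ncol = length(included),
                dimnames = list(ids, included))
  pairs <- pairs[pairs$phecode %in% included, , drop = FALSE]
  tab[cbind(match(pairs$id, ids), match(pairs$phecode, included))] <- 1L
  defs <- map$phecodes[match(included, map$phecodes$phecode), ]
  list(table = tab,
       phecodes = data.frame(phecode = included,
                             description = defs$description,
                             category = defs$category,
                             n_cases = as.integer(counts[included]),
                             stringsAsFactors = FALSE))
}

# Run one logistic PheWAS fit, returning a one-row result data frame.
# Non-converged or degenerate fits are flagged, never silently dropped.
fit_logistic_one <- function(y, x, covariates, trait, category) {
  out <- data.frame(trait = trait, category = category, model = "logistic",
                    estimate = NA_real_, se = NA_real_, p = NA_real_,
                    n = length(y), n_cases = sum(y),
                    flag = "", stringsAsFactors = FALSE)
  if (sum(y) == 0 || sum(y) == length(y)) {
    out$flag <- "degenerate: single-class outcome"
    return(out)
  }
  dat <- data.frame(y = y, prs = x, covariates)
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
        out$flag <<- paste0(out$flag, conditionMessage(w), "; ")
      }
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) out$flag <- paste0(out$flag, "non-converged; ")
  cf <- summary(fit)$coefficients
  if ("prs" %in% rownames(cf)) {
    out$estimate <- cf["prs", 1]
    out$se <- cf["prs", 2]
    out$p <- cf["prs", 4]
  } else {
    out$flag <- paste0(out$flag, "prs coefficient dropped; ")
  }
  out
}

#' Logistic PheWAS of a PRS z-score against phecodes
#'
#' Per phecode, a maximum-likelihood logistic regression of case status on
#' the PRS z-score plus covariates (by default the first 10 genetic
#' principal components and age). The estimate is the log-odds per SD of
#' PRS with its Wald standard error and p-value.
#'
#' @param prs_z Standardized PRS vector.
#' @param phecode_table Output of [build_phecode_table()].
#' @param covariates Data frame/matrix of covariates (same row order).
#' @return Data frame of association results, one row per phecode.
#' @export
phewas_logistic <- function(prs_z, phecode_table, covariates) {
  tab <- phecode_table$table
  stopifnot(length(prs_z) == nrow(tab))
  covariates <- as.data.frame(covariates)
  res <- lapply(seq_len(ncol(tab)), function(j) {
    fit_logistic_one(tab[, j], prs_z, covariates,
                     phecode_table$phecodes$phecode[j],
                     phecode_table$phecodes$category[j])
  })
  do.call(rbind, res)
}

#' Sex-specific statin correction factors
#'
#' For individuals on statins at the first repeat visit and not at
#' enrolment, the per-individual ratio on-statin value / pre-statin value is
#' averaged within each sex and biomarker; that mean ratio is the
#' correction factor.
#'
#' @param visits Data frame in the layout of [gen_biomarkers()]: columns
#'   `sex`, `biomarker`, `value_enrol`, `value_repeat`, `statin_enrol`,
#'   `statin_repeat`.
#' @return Data frame with columns `sex`, `biomarker`, `factor`, `n`.
#'   Biomarker/sex combinations with no qualifying individuals are reported
#'   with `factor = NA`.
#' @export
statin_correction_factors <- function(visits) {
  req <- c("sex", "biomarker", "value_enrol", "value_repeat",
           "statin_enrol", "statin_repeat")
  stopifnot(all(req %in% names(visits)))
  qual <- visits$statin_repeat & !visits$statin_enrol
  groups <- unique(visits[c("sex", "biomarker")])
  res <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- qual & visits$sex == groups$sex[i] &
      visits$biomarker == groups$biomarker[i]
    ratio <- visits$value_repeat[sel] / visits$value_enrol[sel]
    data.frame(sex = groups$sex[i], biomarker = groups$biomarker[i],
               factor = if (sum(sel) > 0) mean(ratio) else NA_real_,
               n = sum(sel), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Flag biomarkers affected by statin use
#'
#' Among individuals on statins at the first repeat visit only, a linear
#' model of the log ratio pre-statin value / on-statin value against the
#' covariates (Townsend deprivation, PCs, age at enrolment, and the
#' enrolment-to-repeat age difference) tests whether statin initiation
#' shifts the biomarker: the adjusted mean log-ratio (the model intercept
#' with centred covariates) differing from zero at p < alpha / n_traits
#' flags the biomarker for adjustment, separately per sex.
#'
#' @param visits Data frame in the layout of [gen_biomarkers()].
#' @param covariates Data frame of per-row covariates (deprivation, PCs,
#'   ages); centred internally.
#' @param n_traits Number of biomarker traits tested (Bonferroni divisor).
#' @param alpha Family-wise error target.
#' @return Data frame with columns `sex`, `biomarker`, `estimate`, `p`,
#'   `flagged`, `n`.
#' @export
flag_statin_affected <- function(visits, covariates = NULL, n_traits = 34,
                                 alpha = 0.05) {
  qual <- visits$statin_repeat & !visits$statin_enrol
  thr <- alpha / n_traits
  groups <- unique(visits[c("sex", "biomarker")])
  res <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- which(qual & visits$sex == groups$sex[i] &
                   visits$biomarker == groups$biomarker[i])
    out <- data.frame(sex = groups$sex[i], biomarker = groups$biomarker[i],
                      estimate = NA_real_, p = NA_real_, flagged = FALSE,
                      n = length(sel), stringsAsFactors = FALSE)
    if (length(sel) < 3) return(out)
    logratio <- log(visits$value_enrol[sel] / visits$value_repeat[sel])
    if (is.null(covariates)) {
      fit <- stats::lm(logratio ~ 1)
    } else {
      cv <- as.data.frame(covariates)[sel, , drop = FALSE]
      cv <- as.data.frame(scale(cv, scale = FALSE))
      fit <- stats::lm(logratio ~ ., data = cv)
    }
    cf <- summary(fit)$coefficients
    out$estimate <- cf["(Intercept)", 1]
    out$p <- cf["(Intercept)", 4]
    out$flagged <- is.finite(out$p) && out$p < thr
    out
  })
  do.call(rbind, res)
}

#' Adjust enrolment biomarker values for statin use
#'
#' For individuals on statins at enrolment, the enrolment value of each
#' flagged biomarker is divided by the corresponding sex-specific
#' correction factor; all other values are returned unchanged.
#'
#' @param visits Data frame in the layout of [gen_biomarkers()].
#' @param flags Output of [flag_statin_affected()].
#' @param factors Output of [statin_correction_factors()].
#' @return `visits` with `value_enrol` adjusted.
#' @export
adjust_biomarkers <- function(visits, flags, factors) {
  key <- function(df) paste(df$sex, df$biomarker)
  flagged <- key(flags)[flags$flagged]
  m <- match(key(visits), key(factors))
  fac <- factors$factor[m]
  sel <- visits$statin_enrol & key(visits) %in% flagged
  if (any(sel & is.na(fac))) {
    stop("correction factor undefined for a flagged biomarker",
         call. = FALSE)
  }
  visits$value_enrol[sel] <- visits$value_enrol[sel] / fac[sel]
  visits
}

#' Linear PheWAS of a PRS z-score against biomarkers
#'
#' Biomarker values are natural-log transformed and regressed on the PRS
#' z-score plus covariates (fasting time, age at measurement, PCs); the
#' estimate is the log-scale change per SD of PRS. Nonpositive biomarker
#' values are rejected.
#'
#' @param prs_z Standardized PRS vector.
#' @param values Named list or data frame of biomarker value vectors
#'   (already statin-adjusted), or a single numeric vector.
#' @param covariates Data frame of covariates.
#' @param log_transform Apply the natural-log transform (default TRUE).
#' @return Data frame of association results, one row per biomarker.
#' @export
phewas_biomarkers <- function(prs_z, values, covariates,
                              log_transform = TRUE) {
  if (is.numeric(values)) values <- list(biomarker = values)
  covariates <- as.data.frame(covariates)
  res <- lapply(names(values), function(nm) {
    y <- values[[nm]]
    stopifnot(length(y) == length(prs_z))
    if (log_transform) {
      if (any(y <= 0, na.rm = TRUE)) {
        stop(sprintf("nonpositive values in biomarker %s", nm),
             call. = FALSE)
      }
      y <- log(y)
    }
    dat <- data.frame(y = y, prs = prs_z, covariates)
    fit <- stats::lm(y ~ ., data = dat)
    cf <- summary(fit)$coefficients
    data.frame(trait = nm, category = "biomarker", model = "linear",
               estimate = cf["prs", 1], se = cf["prs", 2],
               p = cf["prs", 4], n = sum(!is.na(y)), n_cases = NA_integer_,
               flag = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Quality control of female-specific reproductive factors
#'
#' Applies the per-factor plausibility windows: age at menarche within
#' 8-20, age at first live birth within 14-43, age at menopause within
#' 40-63 (earlier or later excluded), menstrual cycle length within 22-36
#' days, first-child birth weight within 3-12 pounds. Parity of four or
#' more live births is collapsed into a single "4+" category. With repeated
#' visits, the last recorded value is used for parity and the first for all
#' other factors. Out-of-window values become NA (each factor is analysed
#' separately).
#'
#' @param factors Data frame from [gen_female_factors()]; an optional
#'   `visit` column marks repeated records per id.
#' @return Data frame, one row per id, with `parity` an ordered factor.
#' @export
female_factor_qc <- function(factors) {
  stopifnot("id" %in% names(factors))
  if ("visit" %in% names(factors)) {
    factors <- factors[order(factors$id, factors$visit), , drop = FALSE]
    first <- factors[!duplicated(factors$id), , drop = FALSE]
    last <- factors[!duplicated(factors$id, fromLast = TRUE), , drop = FALSE]
    first$parity <- last$parity[match(first$id, last$id)]
    factors <- first
    factors$visit <- NULL
  }
  window <- function(x, lo, hi) ifelse(!is.na(x) & x >= lo & x <= hi, x,
                                       NA_real_)
  factors$menarche <- window(factors$menarche, 8, 20)
  factors$first_birth_age <- window(factors$first_birth_age, 14, 43)
  factors$menopause <- window(factors$menopause, 40, 63)
  factors$cycle_length <- window(factors$cycle_length, 22, 36)
  factors$birth_weight <- window(factors$birth_weight, 3, 12)
  par_chr <- ifelse(is.na(factors$parity), NA_character_,
                    ifelse(factors$parity >= 4, "4+",
                           as.character(factors$parity)))
  lev <- intersect(c("0", "1", "2", "3", "4+"), unique(par_chr))
  factors$parity <- factor(par_chr, levels = lev, ordered = TRUE)
  rownames(factors) <- NULL
  factors
}

#' Inverse-rank-normal transform
#'
#' Blom offsets: qnorm((rank - 3/8) / (n + 1/4)); ties share the average
#' rank; NAs are preserved.
#'
#' @param x Numeric vector.
#' @return Transformed vector.
#' @export
irnt <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - 3 / 8) / (sum(ok) + 1 / 4))
  out
}

# Default model assignment for the female-specific factors.
female_factor_models <- function() {
  c(menarche = "linear", first_birth_age = "linear",
    menopause = "ordinal", cycle_length = "ordinal",
    parity = "ordinal", birth_weight = "ordinal")
}

#' PheWAS of female-specific reproductive factors
#'
#' Linear factors (age at menarche, age at first live birth) are
#' inverse-rank-normal transformed and fit by ordinary least squares;
#' ordinal factors (age at menopause, cycle length, parity, birth weight)
#' are fit with a proportional-odds logistic model. All p-values come from
#' comparing the t-value to a standard normal. The first 10 PCs are
#' covariates throughout; age at menarche is an additional covariate for
#' age at first live birth.
#'
#' @param prs_z Standardized PRS vector.
#' @param factors QC'd factor table from [female_factor_qc()].
#' @param covariates Data frame of covariates (PCs).
#' @param models Named character vector assigning "linear"/"ordinal" per
#'   factor; defaults to the standard assignment.
#' @return Data frame of association results, one row per factor.
#' @export
phewas_female_factors <- function(prs_z, factors, covariates,
                                  models = female_factor_models()) {
  covariates <- as.data.frame(covariates)
  res <- lapply(names(models), function(nm) {
    if (!nm %in% names(factors)) return(NULL)
    y <- factors[[nm]]
    cv <- covariates
    if (nm == "first_birth_age" && "menarche" %in% names(factors)) {
      cv <- cbind(cv, menarche_cov = factors$menarche)
    }
    ok <- !is.na(y) & stats::complete.cases(cv)
    out <- data.frame(trait = nm, category = "female_factor",
                      model = models[[nm]], estimate = NA_real_,
                      se = NA_real_, p = NA_real_, n = sum(ok),
                      n_cases = NA_integer_, flag = "",
                      stringsAsFactors = FALSE)
    if (models[[nm]] == "linear") {
      dat <- data.frame(y = irnt(as.numeric(y)[ok]), prs = prs_z[ok],
                        cv[ok, , drop = FALSE])
      fit <- stats::lm(y ~ ., data = dat)
      cf <- summary(fit)$coefficients
      out$estimate <- cf["prs", 1]
      out$se <- cf["prs", 2]
      out$p <- 2 * stats::pnorm(-abs(cf["prs", 3]))
    } else {
      yy <- y[ok]
      if (!is.factor(yy)) yy <- factor(yy, ordered = TRUE)
      yy <- droplevels(yy)
      if (nlevels(yy) < 2) {
        stop(sprintf("ordinal factor %s has < 2 levels after QC", nm),
             call. = FALSE)
      }
      dat <- data.frame(y = yy, prs = prs_z[ok], cv[ok, , drop = FALSE])
      fit <- MASS::polr(y ~ ., data = dat, Hess = TRUE)
      cf <- summary(fit)$coefficients
      tval <- cf["prs", "t value"]
      out$estimate <- cf["prs", "Value"]
      out$se <- cf["prs", "Std. Error"]
      out$p <- 2 * stats::pnorm(-abs(tval))
    }
    out
  })
  do.call(rbind, res[!vapply(res, is.null, logical(1))])
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error target.
#' @param n_traits Number of traits in the set (>= 1).
#' @return `alpha / n_traits`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_traits) {
  if (!is_count(n_traits)) stop_param("n_traits must be a positive integer")
  alpha / n_traits
}
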