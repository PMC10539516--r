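#' The seven Mendelian segregation models for a bi-allelic F1 marker
#'
#' With parental genotypes written in the A/B allele alphabet, a bi-allelic
#' marker in an outbred F1 family can segregate in exactly seven ways:
#' AAxAA, BBxBB, AAxBB (uninformative — all offspring identical), AAxAB,
#' BBxAB, ABxAB, and the special case ABxMissing where one parent is
#' heterozygous, the other was not genotyped, and offspring show AA and BB
#' in a 1:1 ratio (AB offspring are incompatible under this model).
#'
#' @return data.frame with columns `name`, `informative`, and list-columns
#'   `expected` (named offspring class ratios over codes "AA"/"AB"/"BB") and
#'   `parents` (the unordered parental genotype configuration, codes 0/1/2,
#'   `NA` = required-missing parent for ABxMissing).
#' @export
segregation_types <- function() {
  data.frame(
    name = c("AAxAA", "BBxBB", "AAxBB", "AAxAB", "BBxAB", "ABxAB", "ABxMissing"),
    informative = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    expected = I(list(
      c(AA = 1), c(BB = 1), c(AB = 1),
      c(AA = 1, AB = 1), c(BB = 1, AB = 1),
      c(AA = 1, AB = 2, BB = 1), c(AA = 1, BB = 1)
    )),
    parents = I(list(
      c(0L, 0L), c(2L, 2L), c(0L, 2L), c(0L, 1L), c(2L, 1L), c(1L, 1L),
      c(1L, NA_integer_)
    ))
  )
}

geno_class <- c("AA", "AB", "BB")

#' Tally offspring genotype classes under a segregation model
#'
#' Missing offspring genotypes are excluded entirely; called genotypes
#' outside the model's expected classes are counted as incompatible.
#'
#' @param offspring_geno integer vector of offspring codes (0/1/2/NA).
#' @param seg_type segregation model name (see [segregation_types]).
#' @return list with `class_counts` (named counts over the model's expected
#'   classes) and `incompatible_count`.
#' @export
classify_offspring <- function(offspring_geno, seg_type) {
  st <- segregation_types()
  idx <- match(seg_type, st$name)
  if (is.na(idx)) stop("unknown segregation type: ", seg_type)
  expected <- st$expected[[idx]]
  called <- offspring_geno[!is.na(offspring_geno)]
  cls <- geno_class[called + 1L]
  counts <- vapply(names(expected), function(k) sum(cls == k), integer(1))
  list(class_counts = counts,
       incompatible_count = length(called) - sum(counts))
}

#' Goodness-of-fit test of offspring counts against a segregation model
#'
#' A marker passes a model when (a) the fraction of incompatible offspring
#' genotypes among all called offspring is at most `max_error` (the 2%
#' erroneous-genotype allowance; e.g. at most 2% BB offspring from an ABxAA
#' cross), and (b) for multi-class models, a chi-square goodness-of-fit of
#' the compatible class counts against the expected ratios (no continuity
#' correction, df = classes - 1) is not rejected at `alpha`. Single-class
#' models (AAxAA, BBxBB, AAxBB) have df 0: only the error criterion applies
#' and the chi-square is reported as `NA`.
#'
#' @param class_counts named counts over the model's expected classes.
#' @param incompatible_count called offspring outside those classes.
#' @param seg_type model name.
#' @param max_error maximum tolerated incompatible fraction (default 0.02).
#' @param alpha chi-square rejection level (default 0.005).
#' @return list with `chi2`, `df`, `p`, `error_fraction`, `pass` and
#'   `reason` when failing.
#' @export
test_segregation <- function(class_counts, incompatible_count, seg_type,
                             max_error = 0.02, alpha = 0.005) {
  st <- segregation_types()
  idx <- match(seg_type, st$name)
  if (is.na(idx)) stop("unknown segregation type: ", seg_type)
  expected <- st$expected[[idx]]
  stopifnot(all(class_counts >= 0), incompatible_count >= 0)
  n_comp <- sum(class_counts)
  n_called <- n_comp + incompatible_count
  if (n_called == 0L) {
    return(list(chi2 = NA_real_, df = 0L, p = NA_real_,
                error_fraction = NA_real_, pass = FALSE,
                reason = "no called offspring"))
  }
  err <- incompatible_count / n_called
  if (length(expected) == 1L) {
    pass <- err <= max_error
    return(list(chi2 = NA_real_, df = 0L, p = NA_real_, error_fraction = err,
                pass = pass,
                reason = if (pass) NA_character_ else "error fraction"))
  }
  counts <- class_counts[names(expected)]
  ratios <- expected / sum(expected)
  exp_counts <- n_comp * ratios
  if (n_comp == 0L) {
    return(list(chi2 = NA_real_, df = length(expected) - 1L, p = NA_real_,
                error_fraction = err, pass = FALSE,
                reason = "no compatible offspring"))
  }
  chi2 <- sum((counts - exp_counts)^2 / exp_counts)
  df <- length(expected) - 1L
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  pass <- err <= max_error && p >= alpha
  list(chi2 = chi2, df = df, p = p, error_fraction = err, pass = pass,
       reason = if (pass) NA_character_ else if (err > max_error)
         "error fraction" else "distorted")
}

# Is the observed (possibly missing) parent pair compatible with a model's
# parental configuration? Order-agnostic. Returns a list: compatible flag and
# (when one missing parent had to be imputed) which parent and the imputed
# code. ABxMissing is special: it REQUIRES exactly one called AB parent and
# one missing parent, with no imputation.
parent_compatibility <- function(seg_type, cfg, mother_gt, father_gt) {
  obs <- c(mother = mother_gt, father = father_gt)
  n_miss <- sum(is.na(obs))
  if (seg_type == "ABxMissing") {
    ok <- n_miss == 1L && stats::na.omit(obs) == 1L
    return(list(compatible = ok, corrected = NULL))
  }
  if (n_miss == 0L) {
    ok <- all(sort(obs) == sort(cfg))
    return(list(compatible = ok, corrected = NULL))
  }
  if (n_miss == 2L) return(list(compatible = FALSE, corrected = NULL))
  present <- obs[!is.na(obs)]
  missing_name <- names(obs)[is.na(obs)]
  # impute the missing parent with whichever partner completes the config
  if (present == cfg[1L]) {
    return(list(compatible = TRUE,
                corrected = list(parent = missing_name, genotype = cfg[2L])))
  }
  if (present == cfg[2L]) {
    return(list(compatible = TRUE,
                corrected = list(parent = missing_name, genotype = cfg[1L])))
  }
  list(compatible = FALSE, corrected = NULL)
}

#' Assign a segregation model to one marker
#'
#' Tests the offspring genotype counts against all seven models. Markers
#' passing no model are highly distorted and removed. Among passing models,
#' one is parent-compatible when both observed parent genotypes match its
#' (unordered) parental configuration, or exactly one parent is missing and
#' imputing it creates the match (recorded as `corrected_parent`);
#' ABxMissing is compatible only when exactly one parent is a called AB and
#' the other is missing. Exactly one parent-compatible passing model is
#' assigned; zero removes the marker as a parent mismatch; several remove it
#' as ambiguous (no best-fit tie-break is invented — the counts make the
#' choice auditable).
#'
#' @param mother_gt,father_gt parental codes (0/1/2 or NA).
#' @param offspring_geno integer vector of offspring codes.
#' @param max_error,alpha passed to [test_segregation].
#' @return list with `assigned_type` (name or `NA`), `action` (one of
#'   `"retain"`, `"remove_distorted"`, `"remove_uninformative"`,
#'   `"remove_parent_mismatch"`, `"remove_ambiguous"`), `corrected_parent`
#'   (`NULL` or list(parent, genotype)), `tests` (per-model results), and
#'   `incompatible` (logical over offspring; meaningful when retained).
#' @export
assign_segregation <- function(mother_gt, father_gt, offspring_geno,
                               max_error = 0.02, alpha = 0.005) {
  st <- segregation_types()
  tests <- vector("list", nrow(st))
  names(tests) <- st$name
  for (i in seq_len(nrow(st))) {
    cls <- classify_offspring(offspring_geno, st$name[i])
    tests[[i]] <- c(test_segregation(cls$class_counts, cls$incompatible_count,
                                     st$name[i], max_error, alpha),
                    list(class_counts = cls$class_counts,
                         incompatible_count = cls$incompatible_count))
  }
  passing <- st$name[vapply(tests, `[[`, logical(1), "pass")]
  result <- function(type, action, corrected = NULL) {
    incompat <- rep(FALSE, length(offspring_geno))
    if (!is.na(type)) {
      expected <- st$expected[[match(type, st$name)]]
      ok_codes <- match(names(expected), geno_class) - 1L
      incompat <- !is.na(offspring_geno) & !(offspring_geno %in% ok_codes)
    }
    list(assigned_type = type, action = action, corrected_parent = corrected,
         tests = tests, incompatible = incompat)
  }
  if (!length(passing)) return(result(NA_character_, "remove_distorted"))

  compat <- list()
  for (type in passing) {
    cfg <- st$parents[[match(type, st$name)]]
    pc <- parent_compatibility(type, cfg, mother_gt, father_gt)
    if (pc$compatible) compat[[type]] <- pc
  }
  if (length(compat) == 0L) {
    if (is.na(mother_gt) && is.na(father_gt) && length(passing) > 1L) {
      return(result(NA_character_, "remove_ambiguous"))
    }
    return(result(NA_character_, "remove_parent_mismatch"))
  }
  if (length(compat) > 1L) return(result(NA_character_, "remove_ambiguous"))

  type <- names(compat)[1L]
  corrected <- compat[[1L]]$corrected
  informative <- st$informative[match(type, st$name)]
  result(type, if (informative) "retain" else "remove_uninformative", corrected)
}

#' Apply the Mendelian segregation filter to an F1 family
#'
#' Runs [assign_segregation] on every marker. Retained (informative,
#' parent-compatible, undistorted) markers have their incompatible offspring
#' genotypes silenced (set to missing) and any imputed parent genotype
#' written back; distorted, uninformative, parent-mismatched and ambiguous
#' markers are removed. Actions partition the input marker set.
#'
#' @param x a [genotype_matrix] containing a mother, a father and offspring.
#' @param max_error,alpha see [test_segregation].
#' @return list with `matrix` (filtered, silenced), `assessments` (one row
#'   per input marker: `marker_id`, `assigned_type`, `chi2`, `p`,
#'   `error_fraction`, `action`, `corrected_parent`, `n_silenced`),
#'   `silenced` (coordinates data.frame) and `report` (action counts).
#' @export
apply_segregation_filter <- function(x, max_error = 0.02, alpha = 0.005) {
  roles <- x$samples$role
  mi <- which(roles == "mother"); fi <- which(roles == "father")
  oi <- which(roles == "offspring")
  if (!length(oi)) stop("no offspring in sample metadata")
  if (!length(mi)) mi <- NA_integer_
  if (!length(fi)) fi <- NA_integer_

  n_mark <- nrow(x$geno)
  assessments <- data.frame(
    marker_id = x$markers$marker_id,
    assigned_type = NA_character_, chi2 = NA_real_, p = NA_real_,
    error_fraction = NA_real_, action = NA_character_,
    corrected_parent = NA_character_, n_silenced = 0L
  )
  silenced <- list()
  for (i in seq_len(n_mark)) {
    m_gt <- if (is.na(mi)) NA_integer_ else x$geno[i, mi]
    f_gt <- if (is.na(fi)) NA_integer_ else x$geno[i, fi]
    a <- assign_segregation(m_gt, f_gt, x$geno[i, oi], max_error, alpha)
    assessments$assigned_type[i] <- a$assigned_type
    assessments$action[i] <- a$action
    if (!is.na(a$assigned_type)) {
      tt <- a$tests[[a$assigned_type]]
      assessments$chi2[i] <- tt$chi2
      assessments$p[i] <- tt$p
      assessments$error_fraction[i] <- tt$error_fraction
    }
    if (!is.null(a$corrected_parent)) {
      assessments$corrected_parent[i] <- sprintf(
        "%s=%s", a$corrected_parent$parent,
        geno_class[a$corrected_parent$genotype + 1L])
      pj <- if (a$corrected_parent$parent == "mother") mi else fi
      if (!is.na(pj) && a$action == "retain") {
        x$geno[i, pj] <- a$corrected_parent$genotype
        if (!is.null(x$depth) && x$depth[i, pj] == 0L) x$depth[i, pj] <- NA_integer_
      }
    }
    if (a$action == "retain" && any(a$incompatible)) {
      w <- oi[a$incompatible]
      assessments$n_silenced[i] <- length(w)
      silenced[[length(silenced) + 1L]] <- data.frame(
        marker_id = x$markers$marker_id[i],
        sample_id = x$samples$sample_id[w])
      x$geno[i, w] <- NA_integer_
      if (!is.null(x$depth)) x$depth[i, w] <- 0L
    }
  }
  keep <- assessments$action == "retain"
  report <- as.data.frame(table(action = assessments$action),
                          stringsAsFactors = FALSE)
  names(report)[2L] <- "n"
  list(matrix = x[keep, ],
       assessments = assessments,
       silenced = if (length(silenced)) do.call(rbind, silenced) else
         data.frame(marker_id = character(), sample_id = character()),
       report = report)
}
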