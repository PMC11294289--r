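# Statistics over profiles: Cochran's Q related-samples test of
# functional independence, longitudinal descriptor series, and
# cross-speaker profile comparison.

#' Related-samples test of functional independence
#'
#' Tests whether emission percentages differ across the four operant
#' conditions, treating the response forms as related samples (each form
#' is probed under every condition). The statistic is Cochran's Q,
#'
#' \deqn{Q_c = (k-1)\,\frac{k \sum_j C_j^2 - N^2}{k N - \sum_i R_i^2},}
#'
#' where `k` is the number of conditions, `C_j` the condition totals,
#' `R_i` the row (response-form) totals, and `N` the grand total.
#' Rows that are all 0 or all 1 carry no information and leave the
#' statistic unchanged. The p-value is the upper chi-square tail on
#' `k - 1` degrees of freedom, or an exact within-row permutation
#' p-value for the small designs typical of a single assessment.
#'
#' @param x A `vox_dataset` or a binary matrix (rows = response forms or
#'   form-by-session blocks, columns = conditions).
#' @param p_method `"asymptotic"` (chi-square reference) or
#'   `"permutation"` (within-row permutations, seeded).
#' @param n_perm Number of permutations for `p_method = "permutation"`.
#' @param seed Seed for the permutation draw.
#' @return An object of classes `vox_independence_test` and `htest` with
#'   fields `statistic`, `parameter` (df), `p.value`, and
#'   `n_informative_rows`. When every row is constant the statistic is
#'   undefined: `statistic` is `NA`, `p.value` is 1, and `degenerate` is
#'   `TRUE`.
#' @examples
#' related_samples_test(vox_fixture("table2"))
#' @export
related_samples_test <- function(x, p_method = c("asymptotic", "permutation"),
                                 n_perm = 2000, seed = 1) {
  p_method <- match.arg(p_method)
  m <- if (inherits(x, "vox_dataset")) vox_matrix(x) else as.matrix(x)
  if (!all(m %in% c(0, 1))) {
    stop("the related-samples design requires a binary matrix", call. = FALSE)
  }
  if (nrow(m) < 2) stop("at least 2 response forms are required", call. = FALSE)
  k <- ncol(m)
  df <- k - 1L
  rs <- rowSums(m)
  informative <- rs > 0 & rs < k
  stat <- cochran_q_statistic(m)
  degenerate <- is.na(stat)
  p <- if (degenerate) {
    1
  } else if (p_method == "asymptotic") {
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  } else {
    permutation_pvalue(m, stat, n_perm = n_perm, seed = seed)
  }
  method <- paste0("Cochran's Q test for related binary samples (",
                   if (p_method == "asymptotic") "asymptotic chi-square"
                   else paste0("within-row permutation, B = ", n_perm),
                   ")")
  structure(list(statistic = c(Q = stat), parameter = c(df = df),
                 p.value = p, method = method,
                 data.name = paste(nrow(m), "response rows x", k, "conditions"),
                 n_informative_rows = sum(informative),
                 degenerate = degenerate),
            class = c("vox_independence_test", "htest"))
}

cochran_q_statistic <- function(m) {
  k <- ncol(m)
  n_tot <- sum(m)
  cj <- colSums(m)
  ri <- rowSums(m)
  denom <- k * n_tot - sum(ri^2)
  if (denom == 0) return(NA_real_)
  (k - 1) * (k * sum(cj^2) - n_tot^2) / denom
}

permutation_pvalue <- function(m, observed, n_perm, seed) {
  with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      perm <- t(apply(m, 1, sample))
      s <- cochran_q_statistic(perm)
      if (!is.na(s) && s >= observed - 1e-12) hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  })
}

#' Longitudinal descriptor series
#'
#' Computes the full descriptor set at each timepoint of a repeated
#' assessment and lays the results out as one row per timepoint (age,
#' axis values, A, centroid, R, Q) — the longitudinal reporting layout.
#'
#' @param ages Strictly increasing ages, as `"YY:MM"` strings or numeric
#'   years.
#' @param values_list List of [axis_values()] (one per age).
#' @param config A [radar_config()]; its `property_radius` is applied at
#'   every timepoint.
#' @param speaker Optional [speaker_record()].
#' @return A list of class `vox_series` with elements `speaker`, `ages`
#'   (numeric years), `descriptors` (list of `vox_descriptors`), and
#'   `table` (tibble).
#' @export
longitudinal_series <- function(ages, values_list, config = radar_config(),
                                speaker = NULL) {
  if (length(ages) != length(values_list) || length(ages) < 1) {
    stop("need one axis-value set per age (at least one timepoint)",
         call. = FALSE)
  }
  age_labels <- if (is.character(ages)) ages else format(ages)
  age_num <- if (is.character(ages)) parse_age(ages) else as.numeric(ages)
  if (any(diff(age_num) <= 0)) {
    stop("ages must be strictly increasing", call. = FALSE)
  }
  descs <- lapply(values_list, describe_profile, config = config)
  tab <- do.call(rbind, lapply(seq_along(descs), function(i) {
    descriptor_table(descs[[i]],
                     speaker_id = if (is.null(speaker)) NA_character_
                                  else speaker$speaker_id,
                     age = age_labels[i])
  }))
  structure(list(speaker = speaker, ages = age_num, age_labels = age_labels,
                 descriptors = descs, table = tab),
            class = "vox_series")
}

#' @export
print.vox_series <- function(x, ...) {
  cat("<longitudinal series>", length(x$ages), "timepoint(s)\n")
  print(x$table, ...)
  invisible(x)
}

#' Compare two language profiles
#'
#' Signed descriptor differences (each reported as `a - b`), the per-axis
#' value differences, and the Euclidean separation of the two centroids.
#' Both descriptor sets must have been computed under the same property
#' radius and axis ordering.
#'
#' @param a,b `vox_descriptors` objects.
#' @return A list of class `vox_comparison` with `delta_A`, `delta_R`,
#'   `delta_Q`, `centroid_separation`, and `axis_deltas` (named; `NA`
#'   where either profile lacks axis values).
#' @examples
#' cfg <- radar_config(12)
#' compare_profiles(describe_profile(axis_values(2, 6, 1, 1), cfg),
#'                  describe_profile(axis_values(8, 6, 9, 4), cfg))
#' @export
compare_profiles <- function(a, b) {
  stopifnot(inherits(a, "vox_descriptors"), inherits(b, "vox_descriptors"))
  same_c <- identical(a$C, b$C) ||
    (is.numeric(a$C) && is.numeric(b$C) && isTRUE(all.equal(a$C, b$C)))
  if (!same_c || !identical(a$ordering, b$ordering)) {
    stop("profiles must share the same property radius C and axis ordering",
         call. = FALSE)
  }
  axes <- a$ordering
  delta_axis <- stats::setNames(rep(NA_real_, length(axes)), axes)
  if (!is.null(a$values) && !is.null(b$values)) {
    delta_axis <- a$values[axes] - b$values[axes]
  }
  sep <- if (anyNA(a$centroid) || anyNA(b$centroid)) NA_real_
         else sqrt(sum((a$centroid - b$centroid)^2))
  structure(list(delta_A = a$A - b$A, delta_R = a$R - b$R,
                 delta_Q = a$Q - b$Q, centroid_separation = sep,
                 axis_deltas = delta_axis),
            class = "vox_comparison")
}

#' @export
print.vox_comparison <- function(x, digits = 2, ...) {
  cat("<profile comparison (a - b)>\n")
  cat(sprintf("  delta A = %.*f   delta R = %.*f   delta Q = %.*f\n",
              digits, x$delta_A, digits, x$delta_R, digits, x$delta_Q))
  cat(sprintf("  centroid separation = %s\n",
              if (is.na(x$centroid_separation)) "NA"
              else sprintf("%.*f", digits, x$centroid_separation)))
  cat("  axis deltas:", paste(names(x$axis_deltas),
                              round(x$axis_deltas, digits),
                              sep = "=", collapse = "  "), "\n")
  invisible(x)
}
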