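#' Ordinal phenotype grading scheme
#'
#' Three strictly increasing score boundaries partition the aberrant-axon
#' pixel-intensity scale into Grades 0-3. The defaults are the published
#' scheme: Grade 0 below 5000 ADU, Grade 1 below 25000, Grade 2 below 45000,
#' Grade 3 above. A score exactly at a boundary is promoted to the higher
#' grade (half-open intervals).
#'
#' @param boundaries numeric length-3 vector of strictly increasing,
#'   non-negative boundaries (ADU).
#' @return Object of class `grading_scheme`.
#' @export
grading_scheme <- function(boundaries = c(5000, 25000, 45000)) {
  if (length(boundaries) != 3L || any(diff(boundaries) <= 0) ||
      any(boundaries < 0))
    stop("boundaries must be 3 strictly increasing non-negative values")
  structure(list(boundaries = as.numeric(boundaries), labels = 0:3),
            class = "grading_scheme")
}

#' Assign phenotypic grades to scores
#'
#' Maps each score to its grade under the half-open scheme
#' `[0,b1) -> 0`, `[b1,b2) -> 1`, `[b2,b3) -> 2`, `[b3,Inf) -> 3`.
#'
#' @param score numeric vector of non-negative pixel-intensity scores (ADU).
#' @param scheme a [grading_scheme()].
#' @return Integer vector of grades 0-3.
#' @export
assign_grade <- function(score, scheme = grading_scheme()) {
  stopifnot(inherits(scheme, "grading_scheme"))
  if (any(!is.finite(score)) || any(score < 0))
    stop("scores must be finite and non-negative")
  findInterval(score, scheme$boundaries)
}

#' Average phenotypic score of a group
#'
#' Arithmetic mean of the per-embryo grades; higher values reflect more
#' severe aberrant dorsal projections.
#'
#' @param grades numeric vector of grades (0-3); at least one.
#' @return The mean grade.
#' @export
aps <- function(grades) {
  if (length(grades) < 1L) stop("empty group")
  if (any(grades < 0 | grades > 3)) stop("grades must lie in 0..3")
  mean(grades)
}

#' Combine scores and metadata into graded embryo records
#'
#' @param scores data.frame with `embryo_id` and `score`.
#' @param meta optional data.frame with `embryo_id`, `treatment`, `dose_ng`,
#'   `replicate`; merged by `embryo_id`.
#' @param scheme a [grading_scheme()].
#' @return data.frame of records with a `grade` column consistent with the
#'   scheme.
#' @export
embryo_records <- function(scores, meta = NULL, scheme = grading_scheme()) {
  stopifnot(all(c("embryo_id", "score") %in% names(scores)))
  rec <- scores
  if (!is.null(meta)) {
    missing <- setdiff(scores$embryo_id, meta$embryo_id)
    if (length(missing))
      stop("metadata missing for embryo(s): ", paste(missing, collapse = ", "))
    rec <- merge(scores, meta, by = "embryo_id", sort = FALSE)
  }
  rec$grade <- assign_grade(rec$score, scheme)
  rec
}

#' Per-treatment group summary: n, a.p.s. and grade distribution
#'
#' @param records data.frame with `treatment` and `grade` columns.
#' @return data.frame with one row per treatment: `treatment`, `n`, `aps`
#'   and the fractions `grade0`..`grade3` (summing to 1).
#' @export
group_summary <- function(records) {
  stopifnot(nrow(records) >= 1L, "grade" %in% names(records))
  if (is.null(records$treatment)) records$treatment <- "all"
  out <- lapply(split(records, records$treatment), function(g) {
    fr <- tabulate(g$grade + 1L, nbins = 4L) / nrow(g)
    data.frame(treatment = g$treatment[1], n = nrow(g), aps = aps(g$grade),
               grade0 = fr[1], grade1 = fr[2], grade2 = fr[3], grade3 = fr[4],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Penetrance of the aberrant phenotype
#'
#' Percentage of embryos satisfying the positive rule; by default an embryo
#' counts as having developed aberrant dorsal axons when its grade is at
#' least 1 (score >= first boundary).
#'
#' @param x data.frame with a `grade` column, or a vector of grades.
#' @param positive_rule predicate on grades; default `grade >= 1`.
#' @return Penetrance in percent (0-100).
#' @export
penetrance <- function(x, positive_rule = function(g) g >= 1) {
  g <- if (is.data.frame(x)) x$grade else x
  if (length(g) < 1L) stop("empty group")
  100 * mean(positive_rule(g))
}

#' Dose-response curve of penetrance across replicates
#'
#' For each dose, penetrance is computed per injection replicate and
#' summarized as mean and standard deviation across replicates; a dose with
#' a single replicate reports its mean with SD missing (`NA`), never zero.
#'
#' @param records data.frame with `dose_ng`, `replicate` and `grade`.
#' @param positive_rule passed to [penetrance()].
#' @return data.frame of class `dose_response_curve`: `dose_ng`,
#'   `penetrance_mean`, `penetrance_sd`, `n_replicates`, `n_embryos`,
#'   ordered by dose.
#' @export
dose_response <- function(records, positive_rule = function(g) g >= 1) {
  stopifnot(all(c("dose_ng", "replicate", "grade") %in% names(records)))
  doses <- sort(unique(records$dose_ng))
  if (length(doses) < 2L) stop("need at least two dose levels")
  rows <- lapply(doses, function(d) {
    sub <- records[records$dose_ng == d, ]
    per_rep <- vapply(split(sub, sub$replicate), penetrance,
                      numeric(1), positive_rule = positive_rule)
    data.frame(dose_ng = d,
               penetrance_mean = mean(per_rep),
               penetrance_sd = if (length(per_rep) > 1L) stats::sd(per_rep)
                               else NA_real_,
               n_replicates = length(per_rep),
               n_embryos = nrow(sub))
  })
  structure(do.call(rbind, rows),
            class = c("dose_response_curve", "data.frame"))
}
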