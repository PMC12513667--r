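#' @importFrom stats rnorm runif qnorm quantile sd var median nobs
#' @importFrom utils read.csv write.csv
NULL

# level sets for the baseline covariate table; first level is the reference
.baseline_levels <- list(
  age_group   = c("18-64", "65plus"),
  sex         = c("female", "male"),
  fbs_cat     = c("lt125", "ge125"),
  bun_cat     = c("lt24", "ge24"),
  tg_cat      = c("lt150", "ge150"),
  tc_cat      = c("lt200", "ge200"),
  hdl_cat     = c("ge40", "lt40"),
  ldl_cat     = c("lt100", "ge100"),
  proteinuria = c("negative", "positive"),
  aki         = c("no", "yes"),
  dm          = c("no", "yes"),
  chd         = c("no", "yes"),
  vd          = c("no", "yes"),
  fhhtn       = c("no", "yes"),
  htn_stage   = c("stage1", "stage2", "crisis"),
  treatment   = c("single", "two_plus")
)

#' Assemble and validate a hypertensive cohort
#'
#' Links the three study tables -- long-format blood-pressure visits, one row
#' per subject of baseline covariates, and one row per subject of follow-up
#' outcome -- into a single validated object.  Validation enforces the
#' structural rules the downstream models rely on: the three tables cover
#' exactly the same subjects, visit times are non-negative and unique within
#' subject, systolic pressure exceeds diastolic wherever both are recorded,
#' and every follow-up time is positive with a 0/1 event code.
#'
#' Retention rules (at least two visits per subject, all visit times before
#' follow-up) are *not* enforced here; they are the job of
#' [apply_eligibility()], so that a freshly loaded cohort may legitimately
#' violate them and be reported on.
#'
#' @param visits data.frame with columns `subject_id`, `time_m`, `sbp`, `dbp`
#'   (pressures in mmHg, `NA` allowed).
#' @param baseline data.frame with `subject_id` plus the baseline covariate
#'   columns (see Details); an optional `baseline_ckd` column (`"no"/"yes"`)
#'   marks subjects with kidney disease already present at diagnosis.
#' @param outcomes data.frame with columns `subject_id`, `followup_m`,
#'   `event`.
#' @return an object of class `cohort`: a list with elements `visits`,
#'   `baseline`, `outcomes`.
#' @seealso [read_cohort()], [apply_eligibility()], [simulate_cohort()]
#' @export
cohort <- function(visits, baseline, outcomes) {
  visits   <- as.data.frame(visits)
  baseline <- as.data.frame(baseline)
  outcomes <- as.data.frame(outcomes)
  need <- function(df, cols, what)
    if (!all(cols %in% names(df)))
      stop(sprintf("%s table is missing required column(s): %s", what,
                   paste(setdiff(cols, names(df)), collapse = ", ")), call. = FALSE)
  need(visits, c("subject_id", "time_m", "sbp", "dbp"), "visits")
  need(baseline, "subject_id", "baseline")
  need(outcomes, c("subject_id", "followup_m", "event"), "outcomes")

  visits$subject_id <- as.character(visits$subject_id)
  baseline$subject_id <- as.character(baseline$subject_id)
  outcomes$subject_id <- as.character(outcomes$subject_id)

  ids_v <- unique(visits$subject_id)
  ids_b <- baseline$subject_id; ids_o <- outcomes$subject_id
  if (anyDuplicated(ids_b)) stop("duplicate subject_id in baseline table")
  if (anyDuplicated(ids_o)) stop("duplicate subject_id in outcomes table")
  miss <- function(a, b, na, nb) {
    d <- setdiff(a, b)
    if (length(d)) stop(sprintf(
      "subject(s) present in %s but not %s: %s", na, nb,
      paste(utils::head(d, 5), collapse = ", ")), call. = FALSE)
  }
  miss(ids_v, ids_b, "visits", "baseline"); miss(ids_b, ids_v, "baseline", "visits")
  miss(ids_v, ids_o, "visits", "outcomes"); miss(ids_o, ids_v, "outcomes", "visits")

  dup <- duplicated(visits[c("subject_id", "time_m")])
  if (any(dup)) stop("duplicate (subject, time) visit rows for subject(s): ",
                     paste(unique(visits$subject_id[dup]), collapse = ", "))
  if (any(visits$time_m < 0)) stop("negative visit time_m")
  both <- !is.na(visits$sbp) & !is.na(visits$dbp)
  if (any(visits$sbp[both] <= visits$dbp[both]))
    stop("sbp <= dbp at visit(s) of subject(s): ",
         paste(unique(visits$subject_id[both][
           visits$sbp[both] <= visits$dbp[both]]), collapse = ", "))
  if (any(!is.finite(outcomes$followup_m)) || any(outcomes$followup_m <= 0))
    stop("followup_m must be positive and finite")
  if (!all(outcomes$event %in% c(0, 1))) stop("event must be 0 or 1")

  for (nm in intersect(names(.baseline_levels), names(baseline))) {
    bad <- !is.na(baseline[[nm]]) & !(baseline[[nm]] %in% .baseline_levels[[nm]])
    if (any(bad))
      stop(sprintf("baseline column '%s' has unknown level(s): %s", nm,
                   paste(unique(baseline[[nm]][bad]), collapse = ", ")))
  }

  visits <- visits[order(visits$subject_id, visits$time_m), , drop = FALSE]
  rownames(visits) <- NULL
  structure(list(visits = visits, baseline = baseline, outcomes = outcomes),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n <- nrow(x$outcomes)
  cat("hypertensive cohort:", n, "subjects,", nrow(x$visits), "visits\n")
  if (n) {
    cat(sprintf("  events: %d (%.1f%%); follow-up %.0f-%.0f months\n",
                sum(x$outcomes$event), 100 * mean(x$outcomes$event),
                min(x$outcomes$followup_m), max(x$outcomes$followup_m)))
    nv <- table(x$visits$subject_id)
    cat(sprintf("  visits per subject: median %d (range %d-%d)\n",
                as.integer(median(nv)), min(nv), max(nv)))
  }
  invisible(x)
}

#' @export
nobs.cohort <- function(object, ...) nrow(object$outcomes)

#' Read the three cohort tables from CSV files
#'
#' Comma-separated, UTF-8, header row required.  Missing blood-pressure
#' values may be encoded as an empty field or the literal `NA`; both are
#' read as missing and written back as empty fields by [write_cohort()].
#'
#' @param visits_path,baseline_path,outcomes_path file paths.
#' @return a validated [cohort()].
#' @export
read_cohort <- function(visits_path, baseline_path, outcomes_path) {
  rd <- function(path, what) {
    if (!file.exists(path)) stop("cannot open ", what, " file: ", path)
    read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE,
             fileEncoding = "UTF-8")
  }
  cohort(rd(visits_path, "visits"), rd(baseline_path, "baseline"),
         rd(outcomes_path, "outcomes"))
}

#' Write a cohort to three CSV files
#'
#' @param x a [cohort()].
#' @param dir output directory (created if absent).
#' @param prefix optional filename prefix.
#' @return invisibly, the three file paths written.
#' @export
write_cohort <- function(x, dir, prefix = "") {
  stopifnot(inherits(x, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("visits.csv", "baseline.csv",
                                           "outcomes.csv")))
  write.csv(x$visits, paths[1], row.names = FALSE, na = "")
  write.csv(x$baseline, paths[2], row.names = FALSE, na = "")
  write.csv(x$outcomes, paths[3], row.names = FALSE, na = "")
  invisible(paths)
}

.subset_cohort <- function(x, keep_ids) {
  cohort(x$visits[x$visits$subject_id %in% keep_ids, , drop = FALSE],
         x$baseline[x$baseline$subject_id %in% keep_ids, , drop = FALSE],
         x$outcomes[x$outcomes$subject_id %in% keep_ids, , drop = FALSE])
}

#' Apply the study eligibility rules
#'
#' Drops subjects with (a) a missing or non-positive follow-up time, (b)
#' fewer than two blood-pressure measurements, or (c) kidney disease already
#' flagged at the start of follow-up (optional `baseline_ckd` column), and
#' additionally any visit recorded at or after the subject's follow-up time
#' causes that subject to be dropped under rule (a) -- an inconsistent
#' outcome record.  The operation is idempotent.
#'
#' @param x a [cohort()].
#' @return a list with elements `cohort` (the retained subjects) and
#'   `report`, an `exclusion_report` counting drops per rule.
#' @export
apply_eligibility <- function(x) {
  stopifnot(inherits(x, "cohort"))
  ids <- x$outcomes$subject_id
  n_input <- length(ids)

  bad_outcome <- ids[!is.finite(x$outcomes$followup_m) |
                       x$outcomes$followup_m <= 0]
  # visits at/after followup make the outcome record inconsistent
  fu <- x$outcomes$followup_m[match(x$visits$subject_id, ids)]
  bad_outcome <- union(bad_outcome,
                       unique(x$visits$subject_id[x$visits$time_m >= fu]))
  nvis <- table(factor(x$visits$subject_id, levels = ids))
  single <- ids[nvis < 2]
  base_ckd <- character(0)
  if ("baseline_ckd" %in% names(x$baseline))
    base_ckd <- x$baseline$subject_id[!is.na(x$baseline$baseline_ckd) &
                                        x$baseline$baseline_ckd == "yes"]
  # rule precedence: inconsistent outcome, then baseline disease, then
  # single measurement (each subject counted once)
  d1 <- bad_outcome
  d2 <- setdiff(base_ckd, d1)
  d3 <- setdiff(single, union(d1, d2))
  keep <- setdiff(ids, c(d1, d2, d3))
  report <- structure(list(
    n_input = n_input,
    n_dropped_by_rule = c(inconsistent_outcome = length(d1),
                          baseline_ckd = length(d2),
                          single_measurement = length(d3)),
    n_retained = length(keep)), class = "exclusion_report")
  list(cohort = .subset_cohort(x, keep), report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("eligibility screen:", x$n_input, "subjects in,", x$n_retained,
      "retained\n")
  for (nm in names(x$n_dropped_by_rule))
    cat(sprintf("  dropped (%s): %d\n", nm, x$n_dropped_by_rule[[nm]]))
  invisible(x)
}

#' Serialize an exclusion report to JSON
#' @param x an `exclusion_report`.
#' @param path file path.
#' @export
write_exclusion_report <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Expected visit grid and complete-case filter
#'
#' The study schedules a blood-pressure measurement every `interval_m`
#' months from diagnosis.  A recorded visit matches grid point \eqn{3q} when
#' `|time_m - 3q| <= tol`; grid points before follow-up with no matching
#' visit, or a matching visit missing either pressure, count as missing.
#' Subjects with any missing scheduled value are dropped (the complete-case
#' analysis of the sensitivity comparison).
#'
#' @param x a [cohort()].
#' @param interval_m scheduled spacing in months (default 3).
#' @param tol matching tolerance in months (default 0.5).
#' @return list with `cohort` (complete cases) and `n_dropped`.
#' @export
complete_case_filter <- function(x, interval_m = 3, tol = 0.5) {
  stopifnot(inherits(x, "cohort"), interval_m > 0)
  ids <- x$outcomes$subject_id
  incomplete <- vapply(ids, function(id) {
    fu <- x$outcomes$followup_m[x$outcomes$subject_id == id]
    grid <- schedule_visits(fu, interval_m)
    v <- x$visits[x$visits$subject_id == id, , drop = FALSE]
    for (g in grid) {
      j <- which(abs(v$time_m - g) <= tol)
      if (!length(j)) return(TRUE)
      j <- j[which.min(abs(v$time_m[j] - g))]
      if (is.na(v$sbp[j]) || is.na(v$dbp[j])) return(TRUE)
    }
    FALSE
  }, logical(1))
  list(cohort = .subset_cohort(x, ids[!incomplete]),
       n_dropped = sum(incomplete))
}

#' Predictive imputation of missing blood-pressure values
#'
#' Replaces each missing systolic/diastolic value by a draw from the fitted
#' subject-conditional normal predictive distribution implied by a linear
#' mixed model: with marginal covariance \eqn{V = Z D Z' + \sigma^2 I} per
#' subject, the missing block given the observed block is normal with the
#' usual conditional mean and Schur-complement covariance.  This is a
#' single-model predictive draw, not chained-equations multiple imputation.
#'
#' @param x a [cohort()] possibly containing missing `sbp`/`dbp` values.
#' @param fits named list with elements `sbp` and `dbp`, each an `lmm_fit`
#'   from [fit_lmm()] estimated on the observed data of this cohort.
#' @param n_imputations number of completed cohorts to draw.
#' @param seed integer seed; draws are reproducible given the seed.
#' @return list of `n_imputations` completed [cohort()] objects.
#' @export
impute_predictive <- function(x, fits, n_imputations = 5, seed = 1) {
  stopifnot(inherits(x, "cohort"), all(c("sbp", "dbp") %in% names(fits)))
  set.seed(seed %% .Machine$integer.max)
  out <- vector("list", n_imputations)
  for (m in seq_len(n_imputations)) {
    v <- x$visits
    for (k in c("sbp", "dbp")) {
      fit <- fits[[k]]
      miss_rows <- which(is.na(v[[k]]))
      for (id in unique(v$subject_id[miss_rows])) {
        rows <- which(v$subject_id == id)
        obs <- rows[!is.na(v[[k]][rows])]
        mis <- rows[is.na(v[[k]][rows])]
        if (!length(obs))
          stop("subject ", id, " has no observed ", k,
               " values; cannot condition")
        t_all <- v$time_m[rows]
        des <- .lmm_subject_design(fit, x, id, t_all)
        mu <- drop(des$X %*% fit$beta)
        V <- des$Z %*% fit$D_hat %*% t(des$Z) +
          fit$sigma2_hat * diag(length(rows))
        io <- match(obs, rows); im <- match(mis, rows)
        Voo <- V[io, io, drop = FALSE]
        Vmo <- V[im, io, drop = FALSE]
        # pseudo-solve keeps the sigma^2 -> 0 limit well defined (the
        # marginal covariance Z D Z' is then rank-deficient)
        w <- .sym_pseudosolve(Voo, (v[[k]][obs] / 10) - mu[io])
        cmean <- mu[im] + drop(Vmo %*% w)
        cvar <- V[im, im, drop = FALSE] -
          Vmo %*% .sym_pseudosolve(Voo, t(Vmo))
        draw <- cmean + drop(.rmvnorm_chol(1, .psd_part(cvar)))
        v[[k]][mis] <- 10 * draw
      }
    }
    # restore the physiological ordering where an imputed value crossed
    # its observed (or imputed) counterpart
    imput <- (is.na(x$visits$sbp) | is.na(x$visits$dbp)) &
      !is.na(v$sbp) & !is.na(v$dbp)
    bad <- which(imput & v$sbp <= v$dbp)
    for (j in bad) {
      if (is.na(x$visits$sbp[j])) v$sbp[j] <- v$dbp[j] + 1
      else v$dbp[j] <- v$sbp[j] - 1
    }
    out[[m]] <- cohort(v, x$baseline, x$outcomes)
  }
  out
}

# solve S x = B for symmetric PSD S, dropping null-space directions
.sym_pseudosolve <- function(S, B) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-12
  V <- e$vectors[, pos, drop = FALSE]
  B <- as.matrix(B)
  V %*% ((t(V) %*% B) / e$values[pos])
}

# nearest PSD part of a symmetric matrix (clips tiny negative eigenvalues)
.psd_part <- function(S) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  e$vectors %*% (ev * t(e$vectors))
}

# draw n rows from N(0, S) via eigen square root (S may be singular)
.rmvnorm_chol <- function(n, S) {
  q <- nrow(S)
  e <- eigen(S, symmetric = TRUE)
  R <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), q)
  matrix(rnorm(n * q), n, q) %*% t(R)
}
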