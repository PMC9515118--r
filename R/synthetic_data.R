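#' Group-level hyperparameters of the generative population
#'
#' Group means are given on the interpretable constrained scale (the scale
#' on which estimates are reported); they are mapped through the inverse
#' transforms before subjects are drawn. Subject standard deviations act on
#' the unconstrained scale, matching the hierarchy used for inference.
#'
#' Defaults are the headline gain-domain estimates (baseline risk
#' preference 1.03, weighting curvature 2.5, consistency 6.68, left-TMS
#' weighting shift 0.61, other shifts 0) with moderate between-subject
#' heterogeneity.
#'
#' @param mu_r0,mu_gamma0,mu_tau0 Group means of the baselines, inside
#'   `(0,5)`, `(0,6)`, `(0,Inf)`.
#' @param mu_dr_right,mu_dr_left Group mean shifts of `r`, inside `(-2,2)`.
#' @param mu_dgamma_right,mu_dgamma_left Shifts of `gamma`, inside
#'   `(-1.5,1.5)`.
#' @param mu_dtau_right,mu_dtau_left Shifts of `tau`, inside `(-5,5)`.
#' @param sigma Unconstrained-scale subject SD(s): either one value for all
#'   parameter types or a named vector over the type names.
#' @return An object of class `"group_hyper"`.
#' @export
group_hyper <- function(mu_r0 = 1.03, mu_gamma0 = 2.5, mu_tau0 = 6.68,
                        mu_dr_right = 0, mu_dr_left = 0,
                        mu_dgamma_right = 0, mu_dgamma_left = 0.61,
                        mu_dtau_right = 0, mu_dtau_left = 0,
                        sigma = 0.25) {
  means <- c(r0 = mu_r0, gamma0 = mu_gamma0, tau0 = mu_tau0,
             dr_right = mu_dr_right, dr_left = mu_dr_left,
             dgamma_right = mu_dgamma_right, dgamma_left = mu_dgamma_left,
             dtau_right = mu_dtau_right, dtau_left = mu_dtau_left)
  tab <- param_table("kahneman_tversky")
  for (k in seq_len(nrow(tab))) {
    m <- means[[tab$name[k]]]
    lo <- tab$lower[k]; hi <- tab$upper[k]
    if (m <= lo || (is.finite(hi) && m >= hi))
      stop(sprintf("%s = %g outside (%g, %g)", tab$name[k], m, lo, hi),
           call. = FALSE)
  }
  if (is.null(names(sigma))) {
    stopifnot(length(sigma) == 1L)
    sigma <- stats::setNames(rep(sigma, nrow(tab)), tab$name)
  }
  stopifnot(all(tab$name %in% names(sigma)), all(sigma > 0))
  structure(list(means = means, sigma = sigma[tab$name]),
            class = "group_hyper")
}

#' Draw subject-level parameters from the population
#'
#' Each subject's unconstrained parameter is normal with mean equal to the
#' (unconstrained) group mean and the group SD, then mapped through the
#' bounded transforms, so every draw respects the parameter-space bounds by
#' construction.
#'
#' @param hyper A [group_hyper()].
#' @param n_subjects Number of subjects.
#' @param seed Optional seed (deterministic draws); `NULL` uses the current
#'   RNG stream.
#' @return A data frame with one row per subject and one column per
#'   parameter type, class `"subject_params"`.
#' @export
draw_subject_params <- function(hyper, n_subjects, seed = NULL) {
  stopifnot(inherits(hyper, "group_hyper"), n_subjects >= 1)
  tab <- param_table("kahneman_tversky")
  with_seed(seed, {
    out <- lapply(seq_len(nrow(tab)), function(k) {
      z_mu <- unconstrain(hyper$means[[tab$name[k]]], tab$lower[k], tab$upper[k])
      z <- stats::rnorm(n_subjects, z_mu, hyper$sigma[[tab$name[k]]])
      constrain(z, tab$lower[k], tab$upper[k])
    })
    names(out) <- tab$name
    out <- as.data.frame(out)
    out <- cbind(subject = seq_len(n_subjects), out)
    class(out) <- c("subject_params", "data.frame")
    out
  })
}

#' Compose condition-specific preference parameters
#'
#' Sham sessions use the baselines; right/left stimulation adds the
#' corresponding subject-level delta. Composed values are truncated below
#' at a small positive floor so that the positive admissible region is
#' respected (the bounds constrain the sampled components, not their sum).
#'
#' @param subject One row of a [draw_subject_params()] table (or any list
#'   with the nine parameter fields).
#' @param condition `"sham"`, `"right"` or `"left"`.
#' @param floor Positive lower truncation for the composed parameters; set
#'   to `NULL` to disable (then a non-positive composed value is an error).
#' @return A [preference_params()].
#' @export
condition_params <- function(subject, condition = c("sham", "right", "left"),
                             floor = 1e-6) {
  condition <- match.arg(condition)
  add <- function(base, delta) {
    v <- base + switch(condition, sham = 0, right = delta[[1]], left = delta[[2]])
    if (is.null(floor)) {
      if (v <= 0) stop("composed parameter is non-positive", call. = FALSE)
      v
    } else max(v, floor)
  }
  preference_params(
    r = add(subject$r0, list(subject$dr_right, subject$dr_left)),
    gamma = add(subject$gamma0, list(subject$dgamma_right, subject$dgamma_left)),
    tau = add(subject$tau0, list(subject$dtau_right, subject$dtau_left))
  )
}

trial_columns <- c("subject", "session", "condition", "domain", "mpl_id",
                   "row_index", "xA_best", "xA_worst", "xB_best", "xB_worst",
                   "p_best", "choice")

#' Simulate a full within-subject experiment
#'
#' For each subject: three sessions, one per condition, condition order
#' counterbalanced by a Latin-square rotation over the six orders; each
#' session presents a freshly randomized 96-question design; choices are
#' Bernoulli draws from the Luce choice rule with the subject's
#' condition-composed parameters.
#'
#' @param hyper A [group_hyper()].
#' @param n_subjects Number of subjects.
#' @param outcome_sets Three gain outcome quadruples (see [build_session()]).
#' @param family One of [weighting_families()] (generating family).
#' @param seed Integer seed for the whole simulation.
#' @return A data frame of trial records (one row per subject, session and
#'   question) with a `subject_params` attribute holding the generating
#'   subject parameters.
#' @export
simulate_dataset <- function(hyper, n_subjects,
                             outcome_sets = default_outcome_sets(),
                             family = "kahneman_tversky", seed = NULL) {
  family <- match_family(family)
  with_seed(seed, {
    subjects <- draw_subject_params(hyper, n_subjects)
    orders <- latin_square_orders()
    recs <- vector("list", n_subjects * 3L)
    k <- 0L
    for (i in seq_len(n_subjects)) {
      cond_order <- orders[(i - 1L) %% 6L + 1L, ]
      for (s in seq_len(3L)) {
        cond <- cond_order[s]
        params <- condition_params(subjects[i, ], cond)
        design <- build_session(outcome_sets)
        pa <- choice_prob_rows(design, params, family)
        choice <- ifelse(stats::runif(nrow(design)) < pa, "A", "B")
        k <- k + 1L
        recs[[k]] <- cbind(
          data.frame(subject = i, session = s, condition = cond,
                     stringsAsFactors = FALSE),
          as.data.frame(design), choice = choice)
      }
    }
    out <- do.call(rbind, recs)[, trial_columns]
    rownames(out) <- NULL
    attr(out, "subject_params") <- subjects
    out
  })
}

# vectorized choice probabilities over the rows of a design table
choice_prob_rows <- function(design, params, family) {
  w <- prob_weight(design$p_best,
                   if (family == "linear") 1 else params$gamma, family)
  u <- function(x) sign(x) * abs(x)^params$r
  eu_a <- w * u(design$xA_best) + (1 - w) * u(design$xA_worst)
  eu_b <- w * u(design$xB_best) + (1 - w) * u(design$xB_worst)
  if (any(eu_a * eu_b <= 0))
    stop("weighted utilities must be nonzero and share a sign", call. = FALSE)
  s <- ifelse(design$domain == "gain", 1, -1)
  stats::plogis(s * params$tau / params$r * (log(abs(eu_a)) - log(abs(eu_b))))
}

#' Write / read trial records
#'
#' Tab-separated text with a documented header (see `trial_columns` in the
#' package source); `read_trials` validates the schema and the record
#' invariants and reports offending row numbers.
#'
#' @param trials A trial-record data frame.
#' @param path File path.
#' @return `read_trials` returns the validated data frame.
#' @export
write_trials <- function(trials, path) {
  stopifnot(all(trial_columns %in% names(trials)))
  utils::write.table(trials[trial_columns], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  missing <- setdiff(trial_columns, names(trials))
  if (length(missing))
    stop("trial file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad_row <- function(ok, what) {
    if (any(!ok))
      stop(sprintf("%s (rows %s)", what,
                   paste(utils::head(which(!ok), 5L), collapse = ", ")),
           call. = FALSE)
  }
  bad_row(trials$p_best >= 0 & trials$p_best <= 1, "p_best outside [0, 1]")
  bad_row(trials$condition %in% c("sham", "right", "left"),
          "unknown condition label")
  bad_row(trials$domain %in% c("gain", "loss"), "unknown domain label")
  bad_row(trials$choice %in% c("A", "B"), "choice must be A or B")
  bad_row(trials$xA_best >= trials$xA_worst & trials$xB_best >= trials$xB_worst,
          "best outcome smaller than worst outcome")
  dup <- duplicated(trials[c("subject", "session", "mpl_id", "row_index",
                             "domain")])
  bad_row(!dup, "duplicate (subject, session, question) record")
  trials
}
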