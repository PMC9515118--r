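#' Probability grid of the 16-row multiple price list
#'
#' Best-outcome probabilities of the 16 binary questions of one MPL, from 0
#' to 1.
#' @return Numeric vector of length 16.
#' @export
mpl_probability_grid <- function() {
  c(0, .01, .05, .10, .15, .20, .30, .40, .50, .60, .70, .80, .85, .90, .95, 1)
}

#' Build one multiple price list
#'
#' Constructs one binary choice question per grid probability. Option A pays
#' `x_a_best`/`x_a_worst`, option B pays `x_b_best`/`x_b_worst`; both options
#' share the best-outcome probability within a row. Outcomes must not mix
#' signs (pure-gain or pure-loss lists only).
#'
#' @param x_a_best,x_a_worst,x_b_best,x_b_worst Outcomes in monetary units.
#' @param grid Strictly increasing probabilities in `[0, 1]`.
#' @param mpl_id Identifier attached to each pair.
#' @return List of [lottery_pair()] objects, one per grid value.
#' @examples
#' mpl <- build_mpl(260, 180, 350, 50)
#' length(mpl)  # 16
#' @export
build_mpl <- function(x_a_best, x_a_worst, x_b_best, x_b_worst,
                      grid = mpl_probability_grid(), mpl_id = "mpl") {
  if (any(grid < 0 | grid > 1)) stop("grid values must lie in [0, 1]", call. = FALSE)
  if (length(grid) > 1L && any(diff(grid) <= 0))
    stop("grid must be strictly increasing", call. = FALSE)
  xs <- c(x_a_best, x_a_worst, x_b_best, x_b_worst)
  if (any(xs > 0) && any(xs < 0))
    stop("mixed-sign outcomes within one MPL are not allowed", call. = FALSE)
  lapply(seq_along(grid), function(i) {
    lottery_pair(lottery(x_a_best, x_a_worst, grid[i]),
                 lottery(x_b_best, x_b_worst, grid[i]),
                 row_index = i, mpl_id = mpl_id)
  })
}

#' The printed example MPL (gain domain)
#'
#' Option A pays 260/180 MU, option B 350/50 MU, over the standard 16-level
#' probability grid. Option A has the higher expected value in rows 1-9.
#' @return List of 16 [lottery_pair()] objects.
#' @export
example_mpl <- function() build_mpl(260, 180, 350, 50, mpl_id = "mpl1")

#' Default outcome sets for the three gain-domain MPLs
#'
#' Only the first list's outcomes are printed in the task description; the
#' other two are documented defaults in the same 50-500 MU magnitude range,
#' keeping the same structure (the safe option's EV range lies strictly
#' inside the risky option's, so a unique risk-neutral crossover exists).
#' The two extra lists deliberately vary the ratio between the options'
#' best- and worst-outcome scales (narrow-spread versus wide-spread
#' questions): with CRRA utility this ratio is what separates outcome
#' curvature from probability weighting, so a battery whose lists all share
#' one ratio leaves `r` and the weighting curvature jointly unidentified.
#'
#' @return A list of three numeric vectors `c(xA_best, xA_worst, xB_best,
#'   xB_worst)`.
#' @export
default_outcome_sets <- function() {
  list(mpl1 = c(260, 180, 350, 50),
       mpl2 = c(340, 300, 380, 240),
       mpl3 = c(250, 120, 450, 50))
}

#' Choices of a risk-neutral agent on an MPL
#'
#' Picks the option with the higher expected value in each row; expected
#' value ties break to option A (indifference is not allowed in the task, so
#' a deterministic rule is required).
#'
#' @param mpl List of [lottery_pair()] objects.
#' @return Character vector of `"A"`/`"B"`, one per row.
#' @examples
#' table(risk_neutral_choices(example_mpl()))  # 9 A, 7 B
#' @export
risk_neutral_choices <- function(mpl) {
  vapply(mpl, function(pr) {
    if (expected_value(pr$option_a) >= expected_value(pr$option_b)) "A" else "B"
  }, character(1))
}

latin_square_orders <- function() {
  # all 6 orders of {sham, right, left}: a balanced within-subject rotation
  conds <- c("sham", "right", "left")
  do.call(rbind, lapply(seq_len(6), function(i) {
    p <- rbind(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2),
               c(1, 3, 2), c(3, 2, 1), c(2, 1, 3))[i, ]
    conds[p]
  }))
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Build a 96-question session design
#'
#' Assembles the three gain-domain MPLs plus their sign-mirrored loss twins
#' (96 questions), randomizes which side of the screen holds the
#' higher-variance option in exactly half of the questions, and shuffles the
#' presentation order. Deterministic given `seed`.
#'
#' @param outcome_sets List of exactly three gain outcome quadruples
#'   `c(xA_best, xA_worst, xB_best, xB_worst)`; losses are generated by
#'   negation.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A data frame of class `"session_design"` with one row per
#'   question: `mpl_id`, `row_index`, `domain`, `xA_best`, `xA_worst`,
#'   `xB_best`, `xB_worst`, `p_best`.
#' @export
build_session <- function(outcome_sets = default_outcome_sets(), seed = NULL) {
  if (length(outcome_sets) != 3L)
    stop("exactly 3 gain outcome sets are required", call. = FALSE)
  ids <- names(outcome_sets)
  if (is.null(ids)) ids <- paste0("mpl", seq_len(3))
  rows <- list()
  for (m in seq_len(3)) {
    os <- outcome_sets[[m]]
    stopifnot(length(os) == 4L, all(os >= 0))
    mpl <- build_mpl(os[1], os[2], os[3], os[4], mpl_id = ids[m])
    for (pr in mpl) {
      a <- pr$option_a; b <- pr$option_b
      rows[[length(rows) + 1L]] <- data.frame(
        mpl_id = pr$mpl_id, row_index = pr$row_index, domain = "gain",
        xA_best = a$x_best, xA_worst = a$x_worst,
        xB_best = b$x_best, xB_worst = b$x_worst,
        p_best = a$p_best, stringsAsFactors = FALSE)
    }
  }
  gain <- do.call(rbind, rows)
  design <- with_seed(seed, {
    # show the higher-variance option on the A side in half of the
    # questions; the same flips apply to the mirrored loss questions so
    # that loss question k is exactly gain question k with signs changed
    flip <- sample(nrow(gain), nrow(gain) %/% 2L)
    tmp <- gain[flip, c("xB_best", "xB_worst")]
    gain[flip, c("xB_best", "xB_worst")] <- gain[flip, c("xA_best", "xA_worst")]
    gain[flip, c("xA_best", "xA_worst")] <- tmp
    loss <- gain
    loss$domain <- "loss"
    loss$xA_best <- -gain$xA_worst; loss$xA_worst <- -gain$xA_best
    loss$xB_best <- -gain$xB_worst; loss$xB_worst <- -gain$xB_best
    loss$p_best <- 1 - gain$p_best
    both <- rbind(gain, loss)
    both[sample(nrow(both)), , drop = FALSE]
  })
  rownames(design) <- NULL
  class(design) <- c("session_design", "data.frame")
  design
}

design_columns <- c("mpl_id", "row_index", "domain", "xA_best", "xA_worst",
                    "xB_best", "xB_worst", "p_best")

#' Write / read a session design
#'
#' Tab-separated text with a header; round-trips losslessly (probabilities
#' are exact grid decimals).
#'
#' @param design A `session_design` data frame.
#' @param path File path.
#' @return `read_design` returns the validated `session_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(all(design_columns %in% names(design)))
  utils::write.table(as.data.frame(design)[design_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  design <- utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  missing <- setdiff(design_columns, names(design))
  if (length(missing))
    stop("design file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(design$p_best < 0 | design$p_best > 1))
    stop("p_best outside [0, 1]", call. = FALSE)
  class(design) <- c("session_design", "data.frame")
  design
}
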