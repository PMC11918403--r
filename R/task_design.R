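#' Outcome scales for the two task domains
#'
#' Each domain has four strictly ordered outcome levels; the certain option
#' always pays the level-1 outcome. Monetary levels carry dollar amounts
#' used as the objective value V by the classic utility model; medical
#' levels are purely ordinal and have no numeric amount.
#'
#' @param domain "monetary" or "medical".
#' @return A list with elements \code{domain}, \code{labels} (4 ordered
#'   labels), \code{amounts} (dollar amounts for monetary, \code{NA} for
#'   medical) and \code{level_of_certain} (always 1).
#' @examples
#' outcome_scale("monetary")$amounts
#' @export
outcome_scale <- function(domain = c("monetary", "medical")) {
  domain <- match.arg(domain)
  if (domain == "monetary") {
    list(
      domain = domain,
      labels = c("$5", "$8", "$12", "$25"),
      amounts = c(5, 8, 12, 25),
      level_of_certain = 1L
    )
  } else {
    list(
      domain = domain,
      labels = c(
        "slight improvement", "moderate improvement",
        "major improvement", "complete recovery"
      ),
      amounts = rep(NA_real_, 4L),
      level_of_certain = 1L
    )
  }
}

#' Design variants of the risk-and-ambiguity task
#'
#' The in-person variant crosses outcome levels 2-4 with three risky
#' probabilities (25/50/75%) and three ambiguity levels (24/50/74% occluded),
#' four repetitions per cell, plus 12 catch trials, for 84 trials per domain.
#' The online variant halves the repetitions and adds a fully ambiguous
#' (100% occluded) condition; its catch-trial block presents each
#' uncertainty condition once (49 trials total).
#'
#' @param name "in_person" or "online".
#' @return A list describing the variant: repetitions per cell, risky
#'   probabilities, ambiguity levels, and catch repetitions per uncertainty
#'   condition.
#' @export
design_variant <- function(name = c("in_person", "online")) {
  name <- match.arg(name)
  if (name == "in_person") {
    list(
      name = name,
      repetitions_per_cell = 4L,
      risk_probs = c(0.25, 0.5, 0.75),
      ambiguity_levels = c(0.24, 0.5, 0.74),
      catch_reps_per_condition = 2L
    )
  } else {
    list(
      name = name,
      repetitions_per_cell = 2L,
      risk_probs = c(0.25, 0.5, 0.75),
      ambiguity_levels = c(0.24, 0.5, 0.74, 1.0),
      catch_reps_per_condition = 1L
    )
  }
}

#' Build the full trial table for one domain
#'
#' Enumerates every (outcome level, uncertainty condition) cell of the
#' variant at its repetition count, with lottery levels 2-4 on regular
#' trials and the dominated level-1 lottery on catch trials (a chance at the
#' certain outcome itself, used as an attention check). Risky trials have
#' ambiguity 0 and probability in the variant's risky set; ambiguous trials
#' have probability fixed at 0.5 and ambiguity in the variant's ambiguity
#' set. The certain alternative on every trial is the level-1 outcome with
#' P = 1, A = 0.
#'
#' @param variant A [design_variant()] object or its name.
#' @param domain "monetary" or "medical".
#' @param shuffle_seed Optional integer; when given, trial order is a seeded
#'   uniform shuffle, otherwise trials are in enumeration order.
#' @return A data.frame of trials with columns \code{domain},
#'   \code{trial_index}, \code{level}, \code{win_prob}, \code{ambiguity},
#'   \code{is_catch}, \code{repetition} and \code{amount} (NA for medical).
#' @examples
#' d <- build_design("in_person", "monetary")
#' nrow(d)          # 84
#' sum(d$is_catch)  # 12
#' @export
build_design <- function(variant = "in_person",
                         domain = c("monetary", "medical"),
                         shuffle_seed = NULL) {
  if (is.character(variant)) variant <- design_variant(variant)
  if (!is.list(variant) || is.null(variant$risk_probs)) {
    stop("'variant' must be a design_variant() object or its name")
  }
  domain <- match.arg(domain)
  scale <- outcome_scale(domain)

  conds <- rbind(
    data.frame(win_prob = variant$risk_probs, ambiguity = 0),
    data.frame(win_prob = 0.5, ambiguity = variant$ambiguity_levels)
  )

  main <- expand.grid(
    cond = seq_len(nrow(conds)),
    level = 2:4,
    repetition = seq_len(variant$repetitions_per_cell)
  )
  catch <- expand.grid(
    cond = seq_len(nrow(conds)),
    level = 1L,
    repetition = seq_len(variant$catch_reps_per_condition)
  )
  trials <- rbind(
    data.frame(
      level = main$level,
      win_prob = conds$win_prob[main$cond],
      ambiguity = conds$ambiguity[main$cond],
      is_catch = FALSE,
      repetition = main$repetition
    ),
    data.frame(
      level = catch$level,
      win_prob = conds$win_prob[catch$cond],
      ambiguity = conds$ambiguity[catch$cond],
      is_catch = TRUE,
      repetition = catch$repetition
    )
  )

  if (!is.null(shuffle_seed)) {
    # seeded shuffle without touching the caller's RNG state
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(as.integer(shuffle_seed))
    trials <- trials[sample.int(nrow(trials)), , drop = FALSE]
  }

  data.frame(
    domain = domain,
    trial_index = seq_len(nrow(trials)),
    level = as.integer(trials$level),
    win_prob = trials$win_prob,
    ambiguity = trials$ambiguity,
    is_catch = trials$is_catch,
    repetition = as.integer(trials$repetition),
    amount = scale$amounts[trials$level],
    row.names = NULL
  )
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}

#' Tabulate a trial table by design cell
#'
#' Counts trials per (level, win_prob, ambiguity, is_catch) cell; used to
#' validate that a design is balanced.
#'
#' @param trials A trial table from [build_design()].
#' @return A data.frame with one row per occupied cell and a \code{count}
#'   column; counts sum to \code{nrow(trials)}. An empty input yields an
#'   empty table.
#' @export
summarize_design <- function(trials) {
  cols <- c("level", "win_prob", "ambiguity", "is_catch")
  if (!all(cols %in% names(trials))) {
    stop("'trials' must have columns ", paste(cols, collapse = ", "))
  }
  if (nrow(trials) == 0L) {
    out <- trials[0L, cols]
    out$count <- integer(0)
    return(out)
  }
  agg <- stats::aggregate(
    list(count = rep(1L, nrow(trials))),
    by = trials[cols], FUN = sum
  )
  agg[order(agg$is_catch, agg$level, agg$win_prob, agg$ambiguity), ,
    drop = FALSE
  ]
}
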