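# CSV interchange for choice data, comparison tables and fitted posteriors.
# CSV is the interchange format for trial/choice tables, JSON for summary
# results; a fitted posterior is persisted as a directory of plain CSV
# (draws per chain, pointwise log-likelihood) plus a JSON metadata file.

#' Write / read a choice dataset as CSV
#'
#' Columns: subject_id, domain, trial_index, level, win_prob, ambiguity,
#' is_catch, repetition (if present), chose_lottery (if present), amount.
#' When the dataset carries simulated ground-truth agents (attribute
#' \code{"agents"}), they are written to a sibling file
#' \code{<path>_agents.csv} and re-attached on read if that file exists.
#'
#' @param data A trial table or ChoiceDataset.
#' @param path CSV file path.
#' @return \code{write_choice_data} returns \code{path} invisibly;
#'   \code{read_choice_data} returns the data.frame.
#' @export
write_choice_data <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  agents <- attr(data, "agents")
  if (!is.null(agents)) {
    utils::write.csv(agents, .agents_path(path), row.names = FALSE)
  }
  invisible(path)
}

.agents_path <- function(path) {
  sub("\\.csv$", "", path) |> paste0("_agents.csv")
}

#' @rdname write_choice_data
#' @export
read_choice_data <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("is_catch", "chose_lottery")) {
    if (col %in% names(d)) d[[col]] <- as.logical(d[[col]])
  }
  ap <- .agents_path(path)
  if (file.exists(ap)) {
    attr(d, "agents") <- utils::read.csv(ap, stringsAsFactors = FALSE)
  }
  d
}

#' Validate a choice dataset against the task schema
#'
#' Checks column presence and, row by row, value ranges: level is an
#' integer 1-4; risky trials (ambiguity 0) have win_prob in
#' \{0.25, 0.5, 0.75, 1\}; ambiguous trials have win_prob 0.5 and ambiguity
#' in \{0.24, 0.5, 0.74, 1\}; chose_lottery (when present) is binary;
#' catch trials have level 1.
#'
#' @param data A data.frame or a CSV path.
#' @return A data.frame of violations (columns \code{row}, \code{column},
#'   \code{problem}); zero rows means the dataset is well-formed.
#' @export
validate_dataset <- function(data) {
  if (is.character(data)) data <- read_choice_data(data)
  required <- c(
    "subject_id", "domain", "level", "win_prob", "ambiguity", "is_catch"
  )
  viol <- list()
  add <- function(row, column, problem) {
    viol[[length(viol) + 1L]] <<- data.frame(
      row = row, column = column, problem = problem
    )
  }
  missing_cols <- setdiff(required, names(data))
  for (m in missing_cols) add(NA_integer_, m, "missing required column")
  if (length(missing_cols) == 0L) {
    bad <- which(!(data$level %in% 1:4))
    for (r in bad) add(r, "level", sprintf("level %s outside 1..4", data$level[r]))
    bad <- which(!(data$domain %in% c("monetary", "medical")))
    for (r in bad) add(r, "domain", sprintf("unknown domain '%s'", data$domain[r]))
    risky <- !is.na(data$ambiguity) & data$ambiguity == 0
    bad <- which(risky & !(data$win_prob %in% c(0.25, 0.5, 0.75, 1)))
    for (r in bad) {
      add(r, "win_prob", sprintf(
        "risky win_prob %s not in {0.25, 0.5, 0.75, 1}", data$win_prob[r]
      ))
    }
    ambig <- !is.na(data$ambiguity) & data$ambiguity > 0
    bad <- which(ambig & data$win_prob != 0.5)
    for (r in bad) {
      add(r, "win_prob", "ambiguous trials must have win_prob 0.5")
    }
    bad <- which(!(data$ambiguity %in% c(0, 0.24, 0.5, 0.74, 1)))
    for (r in bad) {
      add(r, "ambiguity", sprintf(
        "ambiguity %s not in {0, 0.24, 0.5, 0.74, 1}", data$ambiguity[r]
      ))
    }
    bad <- which(data$is_catch & data$level != 1L)
    for (r in bad) add(r, "level", "catch trials must have level 1")
    if ("chose_lottery" %in% names(data)) {
      bad <- which(!(data$chose_lottery %in% c(TRUE, FALSE)))
      for (r in bad) add(r, "chose_lottery", "must be binary")
    }
  }
  if (length(viol) == 0L) {
    return(data.frame(
      row = integer(0), column = character(0), problem = character(0)
    ))
  }
  do.call(rbind, viol)
}

#' Export a model-comparison table as CSV
#'
#' Writes the comparison in the conventional column layout: Model, Rank,
#' LOO (elpd), p_loo, d_loo, Weight, SE.
#'
#' @param comparison An \code{ordval_comparison} from [compare_models()].
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  stopifnot(inherits(comparison, "ordval_comparison"))
  out <- data.frame(
    Model = comparison$model,
    Rank = comparison$rank,
    LOO = comparison$elpd_loo,
    p_loo = comparison$p_loo,
    d_loo = comparison$d_loo,
    Weight = comparison$weight,
    SE = comparison$se
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Persist / restore a fitted model
#'
#' A fit is stored as a directory of plain-text files: one CSV of draws per
#' chain, the pointwise log-likelihood CSV, the modeled trials CSV and a
#' JSON metadata file (model spec, sampler settings, subjects,
#' diagnostics). \code{load_fit} reconstructs a working \code{ordval_fit}.
#'
#' @param fit An \code{ordval_fit}.
#' @param dir Directory to create/populate.
#' @return \code{save_fit} returns \code{dir} invisibly; \code{load_fit}
#'   returns the fit.
#' @export
save_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "ordval_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(fit$mcmc)) {
    utils::write.csv(as.matrix(fit$mcmc[[i]]),
      file.path(dir, sprintf("chain_%d.csv", i)),
      row.names = FALSE
    )
  }
  utils::write.csv(fit$log_lik, file.path(dir, "log_lik.csv"),
    row.names = FALSE
  )
  utils::write.csv(fit$data, file.path(dir, "trials.csv"), row.names = FALSE)
  meta <- list(
    sv_model = fit$spec$sv_model,
    choice_rule = fit$spec$choice_rule,
    hyperpriors = unclass(fit$spec$hyperpriors),
    settings = unclass(fit$settings),
    subjects = fit$subjects,
    diagnostics = fit$diagnostics[c("max_rhat", "min_ess", "n_divergences")],
    converged = fit$converged
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname save_fit
#' @export
load_fit <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  chain_files <- sort(list.files(dir, "^chain_[0-9]+\\.csv$", full.names = TRUE))
  mcl <- coda::mcmc.list(lapply(chain_files, function(f) {
    m <- as.matrix(utils::read.csv(f, check.names = FALSE))
    coda::mcmc(m)
  }))
  log_lik <- as.matrix(utils::read.csv(file.path(dir, "log_lik.csv"),
    check.names = FALSE
  ))
  dimnames(log_lik) <- NULL
  d <- utils::read.csv(file.path(dir, "trials.csv"), stringsAsFactors = FALSE)
  if ("is_catch" %in% names(d)) d$is_catch <- as.logical(d$is_catch)
  if ("chose_lottery" %in% names(d)) {
    d$chose_lottery <- as.logical(d$chose_lottery)
  }
  spec <- model_spec(meta$sv_model, meta$choice_rule,
    do.call(hyperprior_settings, as.list(meta$hyperpriors))
  )
  settings <- do.call(sampler_settings, as.list(meta$settings))
  structure(
    list(
      mcmc = mcl, log_lik = log_lik,
      diagnostics = diagnostics(mcl),
      spec = spec, settings = settings,
      subjects = meta$subjects, data = d,
      converged = meta$converged
    ),
    class = "ordval_fit"
  )
}
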