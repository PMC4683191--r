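#' Read a behavioral CSV
#'
#' Reads trial-level bandit behavior in the package's CSV dialect — columns
#' `subject_id,group,game,trial,choice,reward`, one row per trial, `game`
#' and `trial` 1-based, `choice` in \{1, 2\}, `reward` in \{0, 1\} — and
#' validates it. Rows may arrive in any order; they are stably sorted by
#' (subject, game, trial). Malformed rows are reported with their file line
#' numbers (header = line 1); incomplete subjects (gaps or duplicates in
#' the game/trial design) are rejected.
#'
#' @param path CSV file path.
#' @return a validated data frame ordered by subject, game, trial.
#' @examples
#' read_behavior_csv(system.file("extdata", "example_behavior.csv",
#'                               package = "banditdbm"))
#' @export
read_behavior_csv <- function(path) {
  stop_if_not(file.exists(path), paste("no such file:", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "game", "trial", "choice", "reward")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  bad <- !(d$choice %in% c(1, 2)) | !(d$reward %in% c(0, 1)) |
    is.na(d$game) | d$game < 1 | is.na(d$trial) | d$trial < 1
  if (any(bad))
    stop("malformed rows at lines: ",
         paste(which(bad) + 1L, collapse = ", "), call. = FALSE)
  d <- d[order(d$subject_id, d$game, d$trial), , drop = FALSE]
  rownames(d) <- NULL
  for (sub in split(d, d$subject_id)) {
    ok <- tryCatch({ subject_arrays(sub); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok))
      stop(sprintf("subject %s: %s", sub$subject_id[1], ok), call. = FALSE)
  }
  d
}

#' Write a behavioral CSV
#'
#' @param data a behavioral data frame (see [read_behavior_csv()] for the
#'   dialect).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_behavior_csv <- function(data, path) {
  need <- c("subject_id", "group", "game", "trial", "choice", "reward")
  stop_if_not(all(need %in% names(data)), "data lacks behavioral columns")
  utils::write.csv(data[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write ground-truth sidecar files for a simulated cohort
#'
#' Stores the hidden generating truth of [simulate_cohort()] output —
#' per-game true arm rates and the agent specs — in two sidecar CSVs,
#' separate from the behavioral file so that inference stays blind to them.
#'
#' @param cohort output of [simulate_cohort()] (with its `truth` attribute).
#' @param rates_path,agents_path output CSV paths.
#' @return invisible list of the two paths.
#' @export
write_ground_truth <- function(cohort, rates_path, agents_path) {
  truth <- attr(cohort, "truth")
  stop_if_not(!is.null(truth), "cohort has no ground-truth attribute")
  rates <- do.call(rbind, lapply(names(truth), function(id) {
    rt <- truth[[id]]$rates
    data.frame(subject_id = id, game = seq_len(nrow(rt)),
               rate_arm1 = rt[, 1], rate_arm2 = rt[, 2])
  }))
  agents <- do.call(rbind, lapply(names(truth), function(id) {
    ag <- truth[[id]]$agent
    pars <- c(list(gamma = ag$dbm$gamma, r = ag$dbm$r), ag$policy$params)
    data.frame(subject_id = id, policy = ag$policy$policy_id,
               param_name = names(pars),
               param_value = unlist(pars, use.names = FALSE))
  }))
  utils::write.csv(rates, rates_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(agents, agents_path, row.names = FALSE, quote = FALSE)
  invisible(list(rates = rates_path, agents = agents_path))
}
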