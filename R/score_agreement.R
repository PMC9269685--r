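#' Binary transfer-quality score table
#'
#' The Transfer Assessment Instrument (TAI) scores a transfer on itemized
#' technique components, `1` for properly executed and `0` for improperly
#' executed. Eleven items are modeled by the upstream classifiers (items 1,
#' 2 and 7-15); this container holds a trials x items grid of their binary
#' scores plus per-trial metadata.
#'
#' @param scores Numeric/integer matrix or data frame (trials x items) with
#'   entries in \{0, 1\}.
#' @param items Integer item ids, default `c(1, 2, 7:15)`.
#' @param trial_id,subject,transfer_type Optional per-trial metadata;
#'   `transfer_type` is one of `"good"`, `"feet"`, `"trunk"`, `"arm"`,
#'   `"fist"` (a proper transfer or one of four deliberate technique
#'   errors).
#' @return A `score_table` object.
#' @export
score_table <- function(scores, items = c(1, 2, 7:15),
                        trial_id = NULL, subject = NULL,
                        transfer_type = NULL) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "integer"
  if (!all(scores %in% c(0L, 1L))) {
    stop("scores must be binary (0 = improper, 1 = proper)", call. = FALSE)
  }
  if (ncol(scores) != length(items)) {
    stop("score matrix has ", ncol(scores), " columns for ",
         length(items), " items", call. = FALSE)
  }
  n <- nrow(scores)
  colnames(scores) <- paste0("item_", items)
  meta <- data.frame(
    trial_id = if (is.null(trial_id)) paste0("trial_", seq_len(n))
               else as.character(trial_id),
    subject = if (is.null(subject)) NA_character_ else as.character(subject),
    transfer_type = if (is.null(transfer_type)) NA_character_
                    else as.character(transfer_type),
    stringsAsFactors = FALSE
  )
  known <- c("good", "feet", "trunk", "arm", "fist")
  bad <- setdiff(stats::na.omit(unique(meta$transfer_type)), known)
  if (length(bad)) {
    stop("unknown transfer type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(scores = scores, items = items, meta = meta),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat("<score_table>", nrow(x$scores), "trials x", length(x$items),
      "items\n")
  invisible(x)
}

#' Default mapping from improper transfer type to targeted items
#'
#' Each deliberately improper technique targets specific score items:
#' feet off the ground -> item 7 (feet position); no trunk lean -> item 13
#' (trunk lean); leading arm too far out -> items 9 and 12 (leading arm
#' before/after transfer); fist grip -> item 11 (leading hand grip).
#' The mapping is overridable wherever it is consumed.
#'
#' @export
IMPROPER_ITEM_MAP <- list(
  feet = 7L, trunk = 13L, arm = c(9L, 12L), fist = 11L
)

#' Ground-truth score table for a planned session
#'
#' Proper (`"good"`) trials score 1 on every item; each improper transfer
#' type zeroes its targeted item(s) per `item_map` and scores 1 elsewhere.
#'
#' @param plan Data frame with columns `trial_id` (optional), `subject`
#'   (optional) and `transfer_type`.
#' @param items Item ids, default the 11 modeled items.
#' @param item_map Named list mapping improper types to targeted item ids;
#'   default [IMPROPER_ITEM_MAP].
#' @return A [score_table()].
#' @export
ground_truth_table <- function(plan, items = c(1, 2, 7:15),
                               item_map = IMPROPER_ITEM_MAP) {
  stopifnot("transfer_type" %in% names(plan))
  known <- c("good", names(item_map))
  bad <- setdiff(unique(plan$transfer_type), known)
  if (length(bad)) {
    stop("unknown transfer type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(plan)
  scores <- matrix(1L, n, length(items))
  for (i in seq_len(n)) {
    tt <- plan$transfer_type[i]
    if (tt != "good") {
      scores[i, match(item_map[[tt]], items)] <- 0L
    }
  }
  score_table(scores, items,
              trial_id = plan$trial_id %||% NULL,
              subject = plan$subject %||% NULL,
              transfer_type = plan$transfer_type)
}

check_aligned <- function(a, b) {
  stopifnot(inherits(a, "score_table"), inherits(b, "score_table"))
  if (!identical(a$items, b$items)) {
    stop("score tables cover different items", call. = FALSE)
  }
  if (nrow(a$scores) != nrow(b$scores)) {
    stop("score tables cover different numbers of trials", call. = FALSE)
  }
  if (!identical(a$meta$trial_id, b$meta$trial_id)) {
    stop("score tables cover different trials", call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-item percent agreement between two score tables
#'
#' Counts, for each item, the trials on which the two tables give the same
#' binary score, and reports `100 * n_agree / n_trials`. The overall rows
#' average the per-item percentages and counts (SD with n-1). Symmetric in
#' its two arguments.
#'
#' @param a,b [score_table()]s over the same trials and items.
#' @return An `agreement_report` list with `per_item` (item, n_agree,
#'   n_disagree, percent_agreement) and `overall` (means and SDs of the
#'   per-item counts and percentages).
#' @export
percent_agreement <- function(a, b) {
  check_aligned(a, b)
  n <- nrow(a$scores)
  agree <- colSums(a$scores == b$scores)
  per_item <- data.frame(
    item = a$items,
    n_agree = as.integer(agree),
    n_disagree = as.integer(n - agree),
    percent_agreement = 100 * agree / n,
    row.names = NULL
  )
  overall <- data.frame(
    statistic = c("mean", "sd"),
    n_agree = c(mean(per_item$n_agree), stats::sd(per_item$n_agree)),
    n_disagree = c(mean(per_item$n_disagree), stats::sd(per_item$n_disagree)),
    percent_agreement = c(mean(per_item$percent_agreement),
                          stats::sd(per_item$percent_agreement))
  )
  structure(list(per_item = per_item, overall = overall, n_trials = n),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>", x$n_trials, "trials\n")
  print(x$per_item, row.names = FALSE)
  cat(sprintf("overall: %.1f%% (SD %.1f)\n",
              x$overall$percent_agreement[1], x$overall$percent_agreement[2]))
  invisible(x)
}

#' Accuracy of predicted scores against ground truth, by transfer type
#'
#' For each (transfer type, item) stratum, the percentage of trials on which
#' the prediction matches the ground truth, together with the full 2x2
#' confusion counts (tp: both 1, tn: both 0, fp: predicted 1 / truth 0,
#' fn: predicted 0 / truth 1). Empty strata are omitted with a warning.
#'
#' @param pred,truth Aligned [score_table()]s; `truth` (or `pred`) must
#'   carry `transfer_type` metadata.
#' @return An `accuracy_report` with data frame `by_stratum` (columns
#'   `transfer_type`, `item`, `n`, `n_match`, `accuracy`, `tp`, `tn`, `fp`,
#'   `fn`).
#' @export
accuracy_vs_truth <- function(pred, truth) {
  check_aligned(pred, truth)
  types <- truth$meta$transfer_type
  if (all(is.na(types))) types <- pred$meta$transfer_type
  if (all(is.na(types))) {
    stop("transfer_type metadata required for stratified accuracy",
         call. = FALSE)
  }
  out <- list()
  for (tt in unique(types)) {
    rows <- which(types == tt)
    if (length(rows) == 0) {
      warning("empty stratum: ", tt)
      next
    }
    p <- pred$scores[rows, , drop = FALSE]
    g <- truth$scores[rows, , drop = FALSE]
    for (j in seq_along(truth$items)) {
      out[[length(out) + 1]] <- data.frame(
        transfer_type = tt,
        item = truth$items[j],
        n = length(rows),
        n_match = sum(p[, j] == g[, j]),
        accuracy = 100 * mean(p[, j] == g[, j]),
        tp = sum(p[, j] == 1 & g[, j] == 1),
        tn = sum(p[, j] == 0 & g[, j] == 0),
        fp = sum(p[, j] == 1 & g[, j] == 0),
        fn = sum(p[, j] == 0 & g[, j] == 1),
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(by_stratum = do.call(rbind, out)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report>\n")
  print(x$by_stratum, row.names = FALSE)
  invisible(x)
}

#' Read / write score tables as CSV
#'
#' Layout: `trial_id, subject, transfer_type, item_<id>...`.
#'
#' @param x A [score_table()].
#' @param path CSV path.
#' @return `read_score_table` returns a [score_table()];
#'   `write_score_table` returns `path` invisibly.
#' @export
write_score_table <- function(x, path) {
  stopifnot(inherits(x, "score_table"))
  df <- cbind(x$meta, as.data.frame(x$scores))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  item_cols <- grep("^item_", names(df), value = TRUE)
  items <- as.integer(sub("^item_", "", item_cols))
  score_table(
    as.matrix(df[item_cols]), items,
    trial_id = df$trial_id %||% NULL,
    subject = df$subject %||% NULL,
    transfer_type = df$transfer_type %||% NULL
  )
}
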