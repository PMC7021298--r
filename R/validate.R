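# Validation against the gold-standard registry: random development/
# validation split, confusion counts, and the five diagnostic metrics
# (sensitivity, specificity, accuracy, PPV, NPV).

# seed-keyed polynomial string hash, platform-stable: folds characters into
# a value < 2^31 - 1 using double arithmetic (exact below 2^53). The
# multiplier is seed-dependent and a final Lehmer step scrambles the order,
# so different seeds give genuinely different permutations even over
# equal-length ids.
.id_hash <- function(ids, seed) {
  m <- 2147483647
  s <- seed %% m
  vapply(ids, function(id) {
    h <- (s * 2654435 + 1013904223) %% m
    for (c in utf8ToInt(id)) {
      # two multiplies per character keep each product below 2^53 while
      # the effective multiplier exceeds m, so near-identical ids (and
      # nearby seeds) still land far apart
      h <- (h * 2654435 + c) %% m
      h <- (h * 48271 + s) %% m
    }
    # final rounds give the trailing characters full avalanche too
    h <- (h * 2654435 + s) %% m
    h <- (h * 48271 + 12345) %% m
    h <- (h * 2654435 + s) %% m
    (h * 48271) %% m
  }, numeric(1), USE.NAMES = FALSE)
}

#' Split episodes into development and validation partitions
#'
#' Deterministic random partition keyed by a hash of each episode id and a
#' user-supplied seed, so the split is reproducible and invariant to row
#' order. The development partition receives `floor(ratio * N)` episodes
#' (N = 40,443 at ratio 0.7 gives 28,310 / 12,133), the validation
#' partition the remainder.
#'
#' @param data A data frame with an `episode_id` column (episodes, flags or
#'   calls).
#' @param ratio Development fraction, strictly between 0 and 1; default 0.7.
#' @param seed Integer seed keying the partition.
#' @return `data` with a `partition` factor column
#'   (`development`/`validation`) added.
#' @export
#' @examples
#' df <- tibble::tibble(episode_id = sprintf("E%03d", 1:10))
#' table(split_dataset(df, ratio = 0.7, seed = 1)$partition)
split_dataset <- function(data, ratio = 0.7, seed = 17L) {
  stopifnot(ratio > 0, ratio < 1, "episode_id" %in% names(data))
  if (anyDuplicated(data$episode_id)) {
    abort("episode_id values must be unique for splitting")
  }
  h <- .id_hash(data$episode_id, seed)
  ord <- order(h, data$episode_id)
  n_dev <- floor(ratio * nrow(data))
  partition <- character(nrow(data))
  partition[ord[seq_len(n_dev)]] <- "development"
  partition[ord[-seq_len(n_dev)]] <- "validation"
  data$partition <- factor(partition, levels = c("development", "validation"))
  data
}

#' Confusion counts of algorithm calls against gold-standard labels
#'
#' Cross-tabulates the algorithm's AIS/non-AIS calls against registry truth:
#' `tp` (AIS call, true AIS), `fp` (AIS call, not AIS), `fn` (non-AIS call,
#' true AIS), `tn` (non-AIS call, not AIS). The two inputs must cover the
#' same episode set; counts are invariant to row order.
#'
#' @param calls A `stroke_calls` tibble (or any data frame with
#'   `episode_id` and `label`). If it already carries `true_ais`, `labels`
#'   may be omitted.
#' @param labels A data frame with `episode_id` and logical `true_ais`.
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(calls, labels = NULL) {
  calls <- as_tibble(calls)
  if (is.null(labels)) {
    if (!"true_ais" %in% names(calls)) {
      abort("no labels: supply `labels` or calls carrying `true_ais`")
    }
    joined <- calls
  } else {
    labels <- as_tibble(labels) %>%
      select(episode_id, true_ais) %>%
      mutate(true_ais = as.logical(true_ais))
    only_calls <- setdiff(calls$episode_id, labels$episode_id)
    only_labels <- setdiff(labels$episode_id, calls$episode_id)
    if (length(only_calls) > 0 || length(only_labels) > 0) {
      abort(paste0(
        "calls and labels must cover the same episodes; ",
        "only in calls: ", paste(head(only_calls, 5), collapse = ", "),
        "; only in labels: ", paste(head(only_labels, 5), collapse = ", ")
      ))
    }
    joined <- calls %>%
      select(-dplyr::any_of("true_ais")) %>%
      inner_join(labels, by = "episode_id")
  }
  called_ais <- joined$label == "AIS"
  tibble(
    tp = sum(called_ais & joined$true_ais),
    fp = sum(called_ais & !joined$true_ais),
    fn = sum(!called_ais & joined$true_ais),
    tn = sum(!called_ais & !joined$true_ais)
  )
}

safe_ratio <- function(num, den) {
  if_else(den > 0, num / den, NA_real_)
}

#' Diagnostic metrics from confusion counts
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
#' `(tp+tn)/total`, PPV `tp/(tp+fp)` and NPV `tn/(tn+fn)` as proportions in
#' `[0, 1]`. Ratios with a zero denominator are `NA`, never 0. Percentage
#' rendering (one decimal) belongs to the reporting layer; see
#' [tidy.stroke_validation()].
#'
#' @param counts A data frame with columns `tp`, `fp`, `fn`, `tn` (one or
#'   more rows).
#' @return `counts` with columns `sensitivity`, `specificity`, `accuracy`,
#'   `ppv`, `npv` added.
#' @export
#' @examples
#' compute_metrics(tibble::tibble(tp = 8, fn = 2, tn = 6, fp = 4))
compute_metrics <- function(counts) {
  counts <- as_tibble(counts)
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(counts)))
  counts %>%
    mutate(
      sensitivity = safe_ratio(tp, tp + fn),
      specificity = safe_ratio(tn, tn + fp),
      accuracy = safe_ratio(tp + tn, tp + fp + fn + tn),
      ppv = safe_ratio(tp, tp + fp),
      npv = safe_ratio(tn, tn + fn)
    )
}

#' Validate algorithm calls on a development/validation split
#'
#' Splits the labelled calls 7:3 (by default) into development and
#' validation partitions, and computes confusion counts and the five
#' diagnostic metrics for each partition and overall.
#'
#' @param calls A `stroke_calls` tibble carrying `true_ais`, or calls plus a
#'   separate `labels` table.
#' @param labels Optional data frame with `episode_id`, `true_ais`.
#' @param ratio Development fraction; default 0.7.
#' @param seed Integer seed keying the split.
#' @return A `stroke_validation` object; see [tidy.stroke_validation()] and
#'   [glance.stroke_validation()].
#' @export
#' @examples
#' cohort <- generate_validation_cohort(sim_config(n_episodes = 300, seed = 3))
#' calls <- cohort$claims |>
#'   build_episodes() |>
#'   link_registry(cohort$registry) |>
#'   extract_identifiers() |>
#'   classify_episodes()
#' validate_algorithm(calls, seed = 3)
validate_algorithm <- function(calls, labels = NULL, ratio = 0.7,
                               seed = 17L) {
  calls <- as_tibble(calls)
  if (!is.null(labels)) {
    labels <- as_tibble(labels) %>%
      select(episode_id, true_ais) %>%
      mutate(true_ais = as.logical(true_ais))
    calls <- calls %>%
      select(-dplyr::any_of("true_ais")) %>%
      inner_join(labels, by = "episode_id")
  }
  if (!"true_ais" %in% names(calls)) {
    abort("calls must carry `true_ais` (or supply `labels`)")
  }
  split <- split_dataset(calls, ratio = ratio, seed = seed)

  one <- function(d, name) {
    confusion_counts(d) %>%
      compute_metrics() %>%
      mutate(partition = name, n = nrow(d), .before = 1)
  }
  report <- bind_rows(
    one(split %>% filter(partition == "development"), "development"),
    one(split %>% filter(partition == "validation"), "validation"),
    one(split, "overall")
  )
  structure(
    list(report = report, ratio = ratio, seed = seed, n = nrow(calls)),
    class = "stroke_validation"
  )
}

#' @export
print.stroke_validation <- function(x, ...) {
  cat("<stroke_validation> n =", x$n, "episodes, development ratio",
      x$ratio, "(seed", paste0(x$seed, ")"), "\n\n")
  r <- x$report
  fmt <- function(p) ifelse(is.na(p), "  NA", sprintf("%5.1f", 100 * p))
  cat(sprintf("  %-12s %6s %6s %6s %6s %6s %6s\n",
              "partition", "n", "sens%", "spec%", "acc%", "PPV%", "NPV%"))
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %-12s %6d %6s %6s %6s %6s %6s\n",
                r$partition[i], r$n[i], fmt(r$sensitivity[i]),
                fmt(r$specificity[i]), fmt(r$accuracy[i]),
                fmt(r$ppv[i]), fmt(r$npv[i])))
  }
  invisible(x)
}

#' Tidy a validation report
#'
#' @param x A `stroke_validation` object.
#' @param percent Render estimates as percentages (0-100) instead of
#'   proportions.
#' @param ... Unused.
#' @return A long tibble with `partition`, `metric`, `estimate`.
#' @export
tidy.stroke_validation <- function(x, percent = FALSE, ...) {
  out <- x$report %>%
    select(partition, sensitivity, specificity, accuracy, ppv, npv) %>%
    tidyr::pivot_longer(-partition, names_to = "metric",
                        values_to = "estimate")
  if (percent) out$estimate <- 100 * out$estimate
  out
}

#' Glance at a validation report
#'
#' @param x A `stroke_validation` object.
#' @param ... Unused.
#' @return A one-row tibble with the overall counts and metrics, `n`,
#'   `ratio` and `seed`.
#' @export
glance.stroke_validation <- function(x, ...) {
  x$report %>%
    filter(partition == "overall") %>%
    select(-partition) %>%
    mutate(ratio = x$ratio, seed = x$seed)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
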