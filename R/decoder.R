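#' Frame-wise SVM decoder for a behaviour pair
#'
#' Discriminates two behaviours from population activity frame by frame.
#' Bouts of each behaviour are first merged into trials (gaps under
#' `merge_gap` seconds fused), frames are balanced by subsampling the
#' larger class so chance is 50%, and a linear support vector machine is
#' evaluated trial-wise: each trial's frames are predicted by a decoder
#' trained on all other trials, and performance is the macro-averaged F1
#' over the aggregated held-out predictions. The shuffle control randomly
#' reassigns class labels to whole trials (preserving trial structure) and
#' repeats the procedure.
#'
#' @param raster a [population_raster()].
#' @param bouts_a,bouts_b [bout_table()]s defining the two classes.
#' @param merge_gap trial-merging gap in seconds (default 5).
#' @param n_shuffles label shuffles (default 20).
#' @param seed integer seed for balancing and shuffles.
#' @param cost SVM cost parameter.
#' @param max_frames_per_class cap on frames retained per class after
#'   balancing (default 400); larger sessions are subsampled so the
#'   SVM stays tractable.
#' @return list with `f1`, `shuffle_f1` (vector), `shuffle_mean`,
#'   `shuffle_sd`, `n_trials`, `n_frames_per_class`; NA with `flag` when a
#'   class is empty after balancing.
#' @export
framewise_svm_decoder <- function(raster, bouts_a, bouts_b, merge_gap = 5,
                                  n_shuffles = 20, seed = 1, cost = 1,
                                  max_frames_per_class = 400) {
  Y <- unclass(raster)
  fr <- attr(raster, "frame_rate")
  T_ <- ncol(Y)
  ma <- merge_bouts(bouts_a, merge_gap)
  mb <- merge_bouts(bouts_b, merge_gap)
  trials <- list()
  add_trials <- function(tbl, lab) {
    iv <- if (nrow(tbl)) interval_union(tbl$start, tbl$stop)
          else data.frame(start = numeric(0), stop = numeric(0))
    for (i in seq_len(nrow(iv))) {
      frames <- (iv$start[i] + 1):min(iv$stop[i], T_)
      trials[[length(trials) + 1]] <<- list(frames = frames, label = lab)
    }
  }
  add_trials(ma, "a"); add_trials(mb, "b")
  # frames claimed by both classes are ambiguous; drop them
  fa <- unlist(lapply(trials, function(t) if (t$label == "a") t$frames))
  fb <- unlist(lapply(trials, function(t) if (t$label == "b") t$frames))
  both <- intersect(fa, fb)
  if (length(both) > 0)
    trials <- lapply(trials, function(t) {
      t$frames <- setdiff(t$frames, both); t
    })
  trials <- Filter(function(t) length(t$frames) > 0, trials)
  labs <- vapply(trials, `[[`, character(1), "label")
  if (!all(c("a", "b") %in% labs)) {
    return(list(f1 = NA_real_, shuffle_f1 = NULL, shuffle_mean = NA_real_,
                shuffle_sd = NA_real_, n_trials = length(trials),
                n_frames_per_class = NULL,
                flag = "a class is empty after merging/balancing"))
  }
  set.seed(derive_seed(seed, 7))
  # balance by subsampling frames of the larger class (within its trials)
  n_a <- sum(lengths(lapply(trials[labs == "a"], `[[`, "frames")))
  n_b <- sum(lengths(lapply(trials[labs == "b"], `[[`, "frames")))
  n_keep <- min(n_a, n_b, max_frames_per_class)
  balance <- function(trials, lab, n_have, n_keep) {
    if (n_have <= n_keep) return(trials)
    idx <- which(labs == lab)
    all_fr <- unlist(lapply(trials[idx], `[[`, "frames"))
    keep_fr <- sort(sample(all_fr, n_keep))
    for (i in idx)
      trials[[i]]$frames <- intersect(trials[[i]]$frames, keep_fr)
    trials
  }
  trials <- balance(trials, "a", n_a, n_keep)
  trials <- balance(trials, "b", n_b, n_keep)
  trials <- Filter(function(t) length(t$frames) > 0, trials)
  labs <- vapply(trials, `[[`, character(1), "label")
  if (!all(c("a", "b") %in% labs)) {
    return(list(f1 = NA_real_, shuffle_f1 = NULL, shuffle_mean = NA_real_,
                shuffle_sd = NA_real_, n_trials = length(trials),
                n_frames_per_class = NULL,
                flag = "a class is empty after merging/balancing"))
  }
  f1 <- decode_trials(Y, trials, labs, cost)
  sh <- vapply(seq_len(n_shuffles), function(s) {
    decode_trials(Y, trials, sample(labs), cost)
  }, numeric(1))
  sh <- sh[is.finite(sh)]
  list(f1 = f1, shuffle_f1 = sh, shuffle_mean = mean(sh),
       shuffle_sd = stats::sd(sh), n_trials = length(trials),
       n_frames_per_class = n_keep, flag = NULL)
}

# leave-one-trial-out linear SVM; macro F1 over aggregated predictions.
# The training set is re-balanced per fold (holding out a trial removes
# frames from one class only; an unbalanced margin would bias held-out
# predictions against the left-out class and push chance below 0.5).
decode_trials <- function(Y, trials, labs, cost) {
  preds <- character(0); truth <- character(0)
  for (i in seq_along(trials)) {
    tr_idx <- setdiff(seq_along(trials), i)
    tr_labs <- labs[tr_idx]
    if (length(unique(tr_labs)) < 2) next
    xtr <- do.call(cbind, lapply(tr_idx, function(j)
      Y[, trials[[j]]$frames, drop = FALSE]))
    ytr <- factor(rep(tr_labs, vapply(tr_idx, function(j)
      length(trials[[j]]$frames), integer(1))), levels = c("a", "b"))
    n_min <- min(table(ytr))
    keep <- unlist(lapply(levels(ytr), function(lv) {
      idx <- which(ytr == lv)
      if (length(idx) > n_min) sample(idx, n_min) else idx
    }))
    xtr <- xtr[, keep, drop = FALSE]; ytr <- ytr[keep]
    fit <- e1071::svm(t(xtr), ytr, kernel = "linear", scale = FALSE,
                      cost = cost)
    xte <- Y[, trials[[i]]$frames, drop = FALSE]
    p <- as.character(stats::predict(fit, t(xte)))
    preds <- c(preds, p)
    truth <- c(truth, rep(labs[i], length(p)))
  }
  if (length(preds) == 0) return(NA_real_)
  mean(c(f1_score(truth, preds, "a"), f1_score(truth, preds, "b")))
}

f1_score <- function(truth, pred, pos) {
  tp <- sum(truth == pos & pred == pos)
  fp <- sum(truth != pos & pred == pos)
  fn <- sum(truth == pos & pred != pos)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}
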