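#' Behavioural bout tables
#'
#' A bout table is an ordered set of annotated behaviour intervals, the
#' standard representation for hand-scored social behaviour. Each row gives
#' the acting animal, a behaviour label, and a half-open frame interval
#' `[start, stop)` (0-based frames at `frame_rate` Hz). Behaviour labels are
#' grouped into functional classes (accepting, resistance, appetitive,
#' copulation, ...) via a grouping map; the default map follows the standard
#' female-mating ethogram: lordose and wiggle are accepting; approach and
#' sniff are appetitive; dart, top-up, kick and turn are resistance; male
#' mount and intromission together constitute copulation.
#'
#' @param actor character vector, one of `"male"`, `"female"`.
#' @param behavior character vector of behaviour labels.
#' @param start,stop integer frame indices, half-open `[start, stop)`.
#' @param frame_rate sampling rate in Hz.
#' @param grouping named list mapping group name to character vector of
#'   labels; defaults to [default_grouping()].
#' @return A `bout_table`: a data.frame with columns
#'   `actor`, `behavior`, `start`, `stop` and attributes `frame_rate` and
#'   `grouping`, sorted by start frame within actor.
#' @export
bout_table <- function(actor = character(), behavior = character(),
                       start = integer(), stop = integer(),
                       frame_rate = 10, grouping = default_grouping()) {
  df <- data.frame(actor = as.character(actor),
                   behavior = as.character(behavior),
                   start = as.numeric(start), stop = as.numeric(stop),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    if (any(df$start >= df$stop))
      stop("every bout must have start < stop")
    bad <- !df$actor %in% c("male", "female")
    if (any(bad)) stop("actor must be 'male' or 'female'")
    df <- df[order(df$actor, df$start), , drop = FALSE]
    rownames(df) <- NULL
    # same-(actor,label) bouts must not overlap
    for (key in unique(paste(df$actor, df$behavior))) {
      sub <- df[paste(df$actor, df$behavior) == key, , drop = FALSE]
      if (nrow(sub) > 1 && any(sub$start[-1] < sub$stop[-nrow(sub)]))
        stop("overlapping bouts for ", key)
    }
  }
  attr(df, "frame_rate") <- frame_rate
  attr(df, "grouping") <- grouping
  class(df) <- c("bout_table", "data.frame")
  df
}

#' Default behaviour grouping map
#'
#' @return Named list of label vectors. Groups: `accept`, `appetitive`,
#'   `resistance`, `copulation` (male), `self_initiated` (female),
#'   `responsive` (female), `social`, `disengaged`, `male_self_initiated`.
#' @export
default_grouping <- function() {
  accept     <- c("lordose", "wiggle")
  appetitive <- c("approach", "sniff")
  resistance <- c("dart", "top_up", "kick", "turn")
  list(
    accept = accept,
    appetitive = appetitive,
    resistance = resistance,
    copulation = c("mount", "intromission"),
    self_initiated = c("approach", "sniff", "check_genital"),
    responsive = c("lordose", "wiggle", "stay", "dart", "top_up", "kick",
                   "turn"),
    social = c(accept, appetitive, resistance),
    disengaged = c("rear", "dig", "chew"),
    male_self_initiated = c("sniff", "mount", "intromission")
  )
}

frame_rate_of <- function(bouts) {
  fr <- attr(bouts, "frame_rate")
  if (is.null(fr)) stop("bout table has no frame_rate attribute")
  fr
}

grouping_of <- function(bouts) {
  g <- attr(bouts, "grouping")
  if (is.null(g)) default_grouping() else g
}

#' Subset a bout table to one actor and/or behaviour group
#'
#' @param bouts a [bout_table()].
#' @param actor optional actor filter.
#' @param group optional group name resolved through the table's grouping
#'   map, or a character vector of raw labels.
#' @return filtered `bout_table`.
#' @export
filter_bouts <- function(bouts, actor = NULL, group = NULL) {
  keep <- rep(TRUE, nrow(bouts))
  if (!is.null(actor)) keep <- keep & bouts$actor == actor
  if (!is.null(group)) {
    gm <- grouping_of(bouts)
    labels <- if (length(group) == 1 && group %in% names(gm)) gm[[group]]
              else group
    keep <- keep & bouts$behavior %in% labels
  }
  out <- bouts[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("frame_rate", "grouping", "class")] <-
    attributes(bouts)[c("frame_rate", "grouping", "class")]
  out
}

# Union of intervals as a logical occupancy vector over [0, n_frames)
occupancy <- function(bouts, n_frames) {
  occ <- logical(n_frames)
  if (nrow(bouts) == 0) return(occ)
  for (i in seq_len(nrow(bouts))) {
    a <- max(0, bouts$start[i]); b <- min(n_frames, bouts$stop[i])
    if (b > a) occ[(a + 1):b] <- TRUE
  }
  occ
}

#' Merge nearby same-label bouts
#'
#' Bouts of the same (actor, behaviour) separated by a gap shorter than
#' `max_gap` seconds are fused into one interval, the standard
#' trial-construction step before decoding. Idempotent.
#'
#' @param bouts a [bout_table()].
#' @param max_gap gap threshold in seconds; gaps strictly smaller are merged.
#' @return merged `bout_table`.
#' @export
merge_bouts <- function(bouts, max_gap) {
  if (max_gap < 0) stop("max_gap must be >= 0")
  fr <- frame_rate_of(bouts)
  gap_frames <- max_gap * fr
  if (nrow(bouts) == 0) return(bouts)
  pieces <- list()
  for (key in unique(paste(bouts$actor, bouts$behavior, sep = "\r"))) {
    parts <- strsplit(key, "\r")[[1]]
    sub <- bouts[bouts$actor == parts[1] & bouts$behavior == parts[2], ,
                 drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    st <- sub$start[1]; en <- sub$stop[1]; rows <- list()
    if (nrow(sub) > 1) {
      for (i in 2:nrow(sub)) {
        if (sub$start[i] - en < gap_frames) {
          en <- max(en, sub$stop[i])
        } else {
          rows[[length(rows) + 1]] <- c(st, en)
          st <- sub$start[i]; en <- sub$stop[i]
        }
      }
    }
    rows[[length(rows) + 1]] <- c(st, en)
    m <- do.call(rbind, rows)
    pieces[[length(pieces) + 1]] <- data.frame(
      actor = parts[1], behavior = parts[2], start = m[, 1], stop = m[, 2],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  bout_table(out$actor, out$behavior, out$start, out$stop,
             frame_rate = fr, grouping = grouping_of(bouts))
}

#' Binned behaviour-group probability
#'
#' Occupancy probability of each behaviour group in consecutive time bins,
#' either as the within-bin frame fraction (`mode = "occupancy"`) or as a
#' binary occurred/not indicator per bin (`mode = "occurrence"`, the
#' trial-fraction mode when averaged over sessions). Groups are multi-label:
#' probabilities need not sum to 1 across groups.
#'
#' @param bouts a [bout_table()].
#' @param n_frames session length in frames.
#' @param bin bin width in seconds (default 20).
#' @param groups character vector of group names (default accept,
#'   appetitive, resistance).
#' @param mode `"occupancy"` or `"occurrence"`.
#' @return matrix bins x groups of probabilities in `[0, 1]`.
#' @export
behavior_probability <- function(bouts, n_frames, bin = 20,
                                 groups = c("accept", "appetitive",
                                            "resistance"),
                                 mode = c("occupancy", "occurrence")) {
  mode <- match.arg(mode)
  fr <- frame_rate_of(bouts)
  bin_frames <- round(bin * fr)
  if (n_frames < bin_frames) stop("session shorter than one bin")
  n_bins <- floor(n_frames / bin_frames)
  out <- matrix(0, n_bins, length(groups),
                dimnames = list(NULL, groups))
  for (g in groups) {
    occ <- occupancy(filter_bouts(bouts, group = g), n_frames)
    for (bidx in seq_len(n_bins)) {
      idx <- ((bidx - 1) * bin_frames + 1):(bidx * bin_frames)
      frac <- mean(occ[idx])
      out[bidx, g] <- if (mode == "occupancy") frac else as.numeric(frac > 0)
    }
  }
  out
}

#' Copulation bout duration and inter-bout-interval statistics
#'
#' Durations of bouts in a group (default male copulation = mount +
#' intromission) and the gaps (IBIs) between consecutive merged bouts of that
#' group, in seconds.
#'
#' @param bouts a [bout_table()].
#' @param group group name (default `"copulation"`).
#' @param actor actor filter (default `"male"`).
#' @return list with `durations`, `ibis` (seconds), `mean_duration`,
#'   `mean_ibi`, `median_ibi`.
#' @export
bout_ibi_stats <- function(bouts, group = "copulation", actor = "male") {
  fr <- frame_rate_of(bouts)
  cop <- filter_bouts(bouts, actor = actor, group = group)
  cop <- cop[order(cop$start), , drop = FALSE]
  durations <- (cop$stop - cop$start) / fr
  # IBI between consecutive copulation bouts irrespective of label; overlap
  # of mount/intromission is first resolved into an interval union
  ibis <- numeric(0)
  if (nrow(cop) >= 2) {
    iv <- interval_union(cop$start, cop$stop)
    if (nrow(iv) >= 2)
      ibis <- (iv$start[-1] - iv$stop[-nrow(iv)]) / fr
  }
  list(durations = durations, ibis = ibis,
       mean_duration = if (length(durations)) mean(durations) else NA_real_,
       mean_ibi = if (length(ibis)) mean(ibis) else NA_real_,
       median_ibi = if (length(ibis)) stats::median(ibis) else NA_real_)
}

interval_union <- function(start, stop) {
  o <- order(start); start <- start[o]; stop <- stop[o]
  us <- start[1]; ue <- stop[1]; rows <- list()
  if (length(start) > 1) {
    for (i in 2:length(start)) {
      if (start[i] <= ue) ue <- max(ue, stop[i])
      else { rows[[length(rows) + 1]] <- c(us, ue); us <- start[i]; ue <- stop[i] }
    }
  }
  rows[[length(rows) + 1]] <- c(us, ue)
  m <- do.call(rbind, rows)
  data.frame(start = m[, 1], stop = m[, 2])
}

#' Self-initiated versus responsive mating time
#'
#' Splits total female mating-behaviour time into the self-initiated
#' (appetitive + check-genital) and male-responsive (accept, resistance,
#' stay) components, and reports the ratio of male to female self-initiated
#' mating time.
#'
#' @param female,male [bout_table()]s for each actor.
#' @return list with `responsive_fraction`, `self_initiated_fraction`
#'   (summing to 1 over female mating time), `male_female_ratio`, and a
#'   `defined` flag (FALSE when the female shows no mating behaviour).
#' @export
initiation_split <- function(female, male) {
  fr <- frame_rate_of(female)
  self_t <- sum_group_time(female, "female", "self_initiated")
  resp_t <- sum_group_time(female, "female", "responsive")
  tot <- self_t + resp_t
  male_t <- sum_group_time(male, "male", "male_self_initiated")
  if (tot == 0) {
    return(list(responsive_fraction = NA_real_,
                self_initiated_fraction = NA_real_,
                male_female_ratio = if (self_t > 0) male_t / self_t else NA_real_,
                defined = FALSE))
  }
  list(responsive_fraction = resp_t / tot,
       self_initiated_fraction = self_t / tot,
       male_female_ratio = if (self_t > 0) male_t / self_t else Inf,
       defined = TRUE)
}

sum_group_time <- function(bouts, actor, group) {
  sub <- filter_bouts(bouts, actor = actor, group = group)
  if (nrow(sub) == 0) return(0)
  iv <- interval_union(sub$start, sub$stop)
  sum(iv$stop - iv$start)
}

#' Female engagement during copulation bouts and IBIs
#'
#' For each male copulation bout and each inter-bout interval, the fraction
#' of time the female spends in social (accept + resistance + appetitive)
#' versus non-social disengaged behaviours; `others` is the remainder.
#'
#' @param female female [bout_table()].
#' @param male male [bout_table()] (copulation bouts taken from it).
#' @param n_frames session length in frames.
#' @return list of two data.frames `bouts` and `ibis`, each with columns
#'   `social`, `disengaged`, `others` per interval, plus means.
#' @export
engagement_fractions <- function(female, male, n_frames) {
  cop <- filter_bouts(male, actor = "male", group = "copulation")
  soc <- occupancy(filter_bouts(female, actor = "female", group = "social"),
                   n_frames)
  dis <- occupancy(filter_bouts(female, actor = "female",
                                group = "disengaged"), n_frames)
  frac_in <- function(iv) {
    if (nrow(iv) == 0)
      return(data.frame(social = numeric(0), disengaged = numeric(0),
                        others = numeric(0)))
    res <- t(vapply(seq_len(nrow(iv)), function(i) {
      idx <- (iv$start[i] + 1):min(iv$stop[i], n_frames)
      s <- mean(soc[idx]); d <- mean(dis[idx] & !soc[idx])
      c(s, d, 1 - s - d)
    }, numeric(3)))
    data.frame(social = res[, 1], disengaged = res[, 2], others = res[, 3])
  }
  ivb <- if (nrow(cop)) interval_union(cop$start, cop$stop)
         else data.frame(start = numeric(0), stop = numeric(0))
  ivi <- if (nrow(ivb) >= 2)
    data.frame(start = ivb$stop[-nrow(ivb)], stop = ivb$start[-1])
  else data.frame(start = numeric(0), stop = numeric(0))
  b <- frac_in(ivb); i <- frac_in(ivi)
  list(bouts = b, ibis = i,
       mean_bout_social = if (nrow(b)) mean(b$social) else NA_real_,
       mean_ibi_social = if (nrow(i)) mean(i$social) else NA_real_)
}
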