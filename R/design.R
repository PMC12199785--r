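#' Generate a pseudorandomized preferential-looking design
#'
#' Builds the trial list for the preferential-looking (looking-while-
#' listening) task: 4 warm-up trials with a single picture alternating
#' left, right, left, right, followed by `n_pairs * 2 * reps_per_picture`
#' test trials. Each pair contributes two pictures (`<pair>_a`, `<pair>_b`)
#' and each picture is the labelled target on `reps_per_picture` trials.
#'
#' Pseudorandomization constraints on test trials:
#' * the same pair never appears on two consecutive trials;
#' * the target side never repeats more than once in a row (no three
#'   consecutive same-side targets); with `strict_side = TRUE` the side
#'   alternates on every trial.
#'
#' An `attention_getter_after` flag marks every 8th trial, after which a
#' child-friendly video clip is shown.
#'
#' @param n_pairs Number of picture pairs (default 8).
#' @param reps_per_picture Times each picture serves as target (default 2).
#' @param seed Integer seed for reproducibility.
#' @param strict_side If `TRUE`, no two consecutive trials share a target
#'   side (the stricter reading of the side constraint).
#' @return A data.frame of trials with columns `trial_index`, `kind`
#'   (`"warmup"`/`"test"`), `pair_id`, `target_word`, `target_side`,
#'   `picture_onset_ms`, `picture_duration_ms`, `sentence_offset_lead_ms`,
#'   `attention_getter_after`.
#' @export
#' @examples
#' d <- gen_plp_design(seed = 1)
#' table(d$kind)
gen_plp_design <- function(n_pairs = 8, reps_per_picture = 2, seed = NULL,
                           strict_side = FALSE) {
  if (n_pairs < 2)
    stop("pseudorandomization constraints are unsatisfiable with fewer than ",
         "2 pairs: the same pair would have to repeat consecutively")
  if (reps_per_picture < 1) stop("reps_per_picture must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  n_test <- n_pairs * 2L * reps_per_picture
  # items: one row per test trial before ordering
  items <- expand.grid(pair = seq_len(n_pairs), pic = c("a", "b"),
                       rep = seq_len(reps_per_picture),
                       KEEP.OUT.ATTRS = FALSE)
  order <- order_without_adjacent(items$pair)
  items <- items[order, , drop = FALSE]
  side <- draw_sides(n_test, strict = strict_side)
  # give each picture's repeats opposite sides where possible (bias control);
  # under strict alternation the sequence is already fixed up to its start
  if (!strict_side)
    side <- balance_item_sides(side, paste0(items$pair, items$pic))

  warm <- data.frame(
    trial_index = 1:4, kind = "warmup", pair_id = NA_character_,
    target_word = paste0("warmup_", 1:4),
    target_side = c("left", "right", "left", "right"),
    stringsAsFactors = FALSE)
  test <- data.frame(
    trial_index = 4L + seq_len(n_test), kind = "test",
    pair_id = paste0("pair", items$pair),
    target_word = paste0("pair", items$pair, "_", items$pic),
    target_side = side, stringsAsFactors = FALSE)
  out <- rbind(warm, test)
  out$picture_onset_ms <- 0
  out$picture_duration_ms <- 2500
  out$sentence_offset_lead_ms <- 250
  out$attention_getter_after <- out$trial_index %% 8L == 0L
  out
}

#' Generate a pseudorandomized mismatch design
#'
#' Each of `n_words` words appears `2 * reps_per_condition` times, half
#' followed by a congruent picture and half by an incongruent picture.
#' Constraints: at most two consecutive trials share a congruency condition,
#' and the same word never appears three times in a row. Attention getters
#' follow every 4th trial. Event times are on the button-press clock:
#' occluder motion onset at +360 ms, motion offset at +760 ms, the revealed
#' object then stays for 1240 ms.
#'
#' @param n_words Number of words (default 16).
#' @param reps_per_condition Trials per word per condition (default 2).
#' @param seed Integer seed.
#' @return A data.frame with columns `trial_index`, `word`, `condition`,
#'   `buttonpress_ms`, `motion_onset_ms`, `motion_offset_ms`,
#'   `object_duration_ms`, `attention_getter_after`.
#' @export
#' @examples
#' d <- gen_mm_design(seed = 7)
#' table(d$condition)
gen_mm_design <- function(n_words = 16, reps_per_condition = 2, seed = NULL) {
  if (n_words < 2)
    stop("pseudorandomization constraints are unsatisfiable with fewer than ",
         "2 words")
  if (!is.null(seed)) set.seed(seed)
  items <- expand.grid(word = seq_len(n_words),
                       condition = c("congruent", "incongruent"),
                       rep = seq_len(reps_per_condition),
                       KEEP.OUT.ATTRS = FALSE)
  n <- nrow(items)
  for (attempt in 1:200) {
    ord <- try_mm_order(items$word, as.character(items$condition))
    if (!is.null(ord)) break
    ord <- NULL
  }
  if (is.null(ord))
    stop("could not satisfy mismatch run-length constraints")
  items <- items[ord, , drop = FALSE]
  data.frame(
    trial_index = seq_len(n),
    word = paste0("word", items$word),
    condition = as.character(items$condition),
    buttonpress_ms = 0,
    motion_onset_ms = 360,
    motion_offset_ms = 760,
    object_duration_ms = 1240,
    attention_getter_after = seq_len(n) %% 4L == 0L,
    stringsAsFactors = FALSE)
}

# Randomized sequencing of item labels such that no two adjacent items share
# a label. Greedy with a feasibility guard (place the majority label when it
# would otherwise become unplaceable); restarts on dead ends.
order_without_adjacent <- function(labels) {
  n <- length(labels)
  for (attempt in 1:500) {
    remaining <- seq_len(n)
    out <- integer(0)
    prev <- NA
    ok <- TRUE
    for (i in seq_len(n)) {
      cand <- remaining[labels[remaining] != prev | is.na(prev)]
      if (!length(cand)) { ok <- FALSE; break }
      counts <- table(labels[remaining])
      slots_left <- n - i + 1L
      maxlab <- names(counts)[which.max(counts)]
      # if one label holds more than half the remaining slots, it must go now
      if (max(counts) * 2L > slots_left + 1L &&
          (is.na(prev) || maxlab != as.character(prev))) {
        cand <- cand[labels[cand] == as.integer(maxlab)]
      }
      pick <- cand[sample.int(length(cand), 1L)]
      out <- c(out, pick)
      prev <- labels[pick]
      remaining <- setdiff(remaining, pick)
    }
    if (ok) return(out)
  }
  stop("could not sequence items without adjacent repeats")
}

# Side sequence with no three consecutive repeats (default) or strict
# alternation (strict = TRUE).
draw_sides <- function(n, strict = FALSE) {
  sides <- character(n)
  for (i in seq_len(n)) {
    if (strict && i > 1) {
      sides[i] <- if (sides[i - 1] == "left") "right" else "left"
    } else if (i > 2 && sides[i - 1] == sides[i - 2]) {
      sides[i] <- if (sides[i - 1] == "left") "right" else "left"
    } else {
      sides[i] <- sample(c("left", "right"), 1L)
    }
  }
  sides
}

# Where a picture's repeated target trials all landed on one side, flip pairs
# of positions when doing so does not break the run-length constraint.
balance_item_sides <- function(side, item) {
  for (it in unique(item)) {
    pos <- which(item == it)
    if (length(pos) < 2 || length(unique(side[pos])) > 1) next
    for (p in pos[-1]) {
      cand <- side
      cand[p] <- if (side[p] == "left") "right" else "left"
      if (max_run(cand) <= 2) { side <- cand; break }
    }
  }
  side
}

max_run <- function(x) if (!length(x)) 0L else max(rle(x)$lengths)

try_mm_order <- function(word, condition) {
  n <- length(word)
  remaining <- seq_len(n)
  out <- integer(0)
  for (i in seq_len(n)) {
    w <- word[out]; cc <- condition[out]
    cand <- remaining
    if (length(out) >= 2) {
      if (w[length(w)] == w[length(w) - 1])
        cand <- cand[word[cand] != w[length(w)]]
      if (cc[length(cc)] == cc[length(cc) - 1])
        cand <- cand[condition[cand] != cc[length(cc)]]
    }
    if (!length(cand)) return(NULL)
    pick <- cand[sample.int(length(cand), 1L)]
    out <- c(out, pick)
    remaining <- setdiff(remaining, pick)
  }
  out
}

#' Check preferential-looking design constraints
#'
#' @param design Output of [gen_plp_design()].
#' @param strict_side Check the strict (no two consecutive same-side) rule.
#' @return `TRUE` if all constraints hold, otherwise a character vector of
#'   violation messages.
#' @export
check_plp_design <- function(design, strict_side = FALSE) {
  test <- design[design$kind == "test", ]
  bad <- character(0)
  if (any(test$pair_id[-1] == test$pair_id[-nrow(test)]))
    bad <- c(bad, "same pair on consecutive trials")
  lim <- if (strict_side) 1L else 2L
  if (max_run(test$target_side) > lim)
    bad <- c(bad, sprintf("target side run exceeds %d", lim))
  counts <- table(test$target_word)
  if (length(unique(counts)) != 1)
    bad <- c(bad, "pictures are not labelled equally often")
  warm <- design[design$kind == "warmup", ]
  if (!identical(warm$target_side, c("left", "right", "left", "right")))
    bad <- c(bad, "warm-up sides do not alternate L,R,L,R")
  if (length(bad)) bad else TRUE
}

#' Check mismatch design constraints
#'
#' @param design Output of [gen_mm_design()].
#' @return `TRUE` or a character vector of violation messages.
#' @export
check_mm_design <- function(design) {
  bad <- character(0)
  if (max_run(design$condition) > 2)
    bad <- c(bad, "more than two consecutive same-condition trials")
  if (max_run(design$word) > 2)
    bad <- c(bad, "same word more than twice in a row")
  tab <- table(design$word, design$condition)
  if (length(unique(c(tab))) != 1)
    bad <- c(bad, "word-by-condition cells are unbalanced")
  if (length(bad)) bad else TRUE
}
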