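#' Count spontaneous alternations
#'
#' An alternation is a run of three consecutive arm entries into three
#' distinct arms. Windows overlap with stride 1, so the sequence A, B, C, A
#' contains two alternations (ABC and BCA).
#'
#' @param entries Character (or factor) vector of arm labels over a 3-arm
#'   alphabet; consecutive duplicates (immediate re-entry) are permitted.
#' @return Integer count of alternation windows.
#' @export
#' @examples
#' count_alternations(c("A", "B", "C", "A", "B", "C")) # 4
count_alternations <- function(entries) {
  entries <- as.character(entries)
  n <- length(entries)
  if (n < 3L) return(0L)
  a <- entries[seq_len(n - 2L)]
  b <- entries[seq_len(n - 2L) + 1L]
  c <- entries[seq_len(n - 2L) + 2L]
  sum(a != b & b != c & a != c)
}

#' Spontaneous-alternation score
#'
#' Percentage of spontaneous alternations out of the number of alternation
#' opportunities:
#' \deqn{\%SA = \frac{\#\,alternations}{\#\,entries - 2} \times 100}
#' Undefined (returned as `NA` with a warning) for fewer than 3 entries.
#'
#' @inheritParams count_alternations
#' @return A one-row tibble with `n_entries`, `n_alternations`, `sa_score`
#'   (percent).
#' @export
#' @examples
#' sa_score(c("A", "B", "C", "B", "A", "C", "A", "B"))$sa_score # 66.67
sa_score <- function(entries) {
  entries <- as.character(entries)
  n <- length(entries)
  alt <- count_alternations(entries)
  if (n < 3L) {
    warn("Fewer than 3 arm entries: %SA is undefined.")
    score <- NA_real_
  } else {
    score <- 100 * alt / (n - 2L)
  }
  tibble::tibble(n_entries = n, n_alternations = alt, sa_score = score)
}

#' Score Y-maze sessions from a long entry table
#'
#' @param data Data frame with columns `subject_id` and `arm`, rows ordered
#'   by entry within subject (an `entry_index` column, if present, defines
#'   the order).
#' @return One row per subject: `subject_id`, `n_entries`,
#'   `n_alternations`, `sa_score`.
#' @export
score_entries <- function(data) {
  if ("entry_index" %in% names(data))
    data <- dplyr::arrange(data, .data$subject_id, .data$entry_index)
  data |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(~ sa_score(.x$arm)) |>
    dplyr::ungroup()
}

#' Simulate a Y-maze arm-entry sequence
#'
#' Markovian generator of arm entries over arms A, B, C. The first two
#' entries are uniform and distinct. Each subsequent entry is, with
#' probability `p_alternate`, an arm distinct from both of the two most
#' recent entries (the unique third arm when those differ; uniform over the
#' two remaining arms when they are the same); otherwise it is drawn
#' uniformly from the two most recent entries. `p_alternate = 1` forces
#' perfect alternation (%SA = 100), `p_alternate = 0` confines the animal to
#' two-arm cycling and re-entries (%SA = 0).
#'
#' @param n_entries Number of entries to generate (>= 2).
#' @param p_alternate Alternation probability in \[0, 1\].
#' @param seed Optional integer seed for reproducibility.
#' @return Character vector of arm labels.
#' @export
simulate_entries <- function(n_entries, p_alternate, seed = NULL) {
  if (p_alternate < 0 || p_alternate > 1)
    abort("`p_alternate` must be in [0, 1].")
  if (n_entries < 2L) abort("`n_entries` must be at least 2.")
  run <- function() {
    arms <- c("A", "B", "C")
    out <- character(n_entries)
    out[1:2] <- sample(arms, 2L)
    for (i in seq(3L, length.out = n_entries - 2L)) {
      last2 <- out[c(i - 1L, i - 2L)]
      if (runif(1) < p_alternate) {
        cand <- setdiff(arms, last2)
        out[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
      } else {
        out[i] <- last2[sample.int(2L, 1L)]
      }
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Expected %SA of the entry-sequence generator
#'
#' Closed-form long-run expectation of the alternation rate of
#' [simulate_entries()]. Tracking whether the two most recent entries are
#' distinct gives a two-state Markov chain whose stationary probability of
#' the "distinct" state is \eqn{2p/(1+p)}; a window is an alternation only
#' from that state (probability `p`), so
#' \deqn{E[\%SA] \to \frac{2 p^2}{1 + p} \times 100.}
#'
#' @param p_alternate Alternation probability.
#' @return Expected %SA (percent) in the long-sequence limit.
#' @export
expected_sa <- function(p_alternate) {
  200 * p_alternate^2 / (1 + p_alternate)
}

#' Alternation probability yielding a target %SA
#'
#' Inverse of [expected_sa()]: solves \eqn{2p^2/(1+p) = a} for
#' \eqn{p \in [0, 1]}.
#'
#' @param sa_pct Target %SA in percent.
#' @return `p_alternate` value.
#' @export
p_alternate_for_sa <- function(sa_pct) {
  a <- sa_pct / 100
  if (any(a < 0 | a > 1)) abort("`sa_pct` must be in [0, 100].")
  (a + sqrt(a^2 + 8 * a)) / 4
}
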