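#' Task conditions
#'
#' The three spoken instructions of the command-following task.
#' @keywords internal
task_conditions <- c("left", "right", "rest")

#' Generate a pseudorandom instruction schedule
#'
#' Builds the auditory task schedule: blocks of 36 trials (12 per
#' instruction: left hand, right hand, rest) in pseudorandom order with no
#' more than three consecutive instructions of the same type (checked across
#' block boundaries as well), each instruction lasting 2 s and followed by a
#' silence drawn uniformly from 4--7 s.
#'
#' @param n_blocks Number of 36-trial blocks (>= 1). Five blocks give the
#'   180-trial session used at the bedside.
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @param instruction_duration Spoken-instruction length in seconds.
#' @param silence_range Length-2 numeric, uniform bounds of the
#'   post-instruction silence in seconds.
#' @param block_size Trials per block; must be divisible by 3.
#' @param start_time Onset of the first instruction, in seconds from the
#'   start of the recording (leaves padding for filter transients).
#' @param max_run Maximum allowed run of identical instructions.
#'
#' @return A data.frame of class `instruction_schedule` with columns
#'   `condition`, `onset_time` (s), `instruction_duration` (s) and
#'   `silence_duration` (s), plus attributes `block_size` and `n_blocks`.
#' @examples
#' sched <- generate_schedule(1, seed = 1)
#' table(sched$condition)
#' @export
generate_schedule <- function(n_blocks, seed,
                              instruction_duration = 2,
                              silence_range = c(4, 7),
                              block_size = 36L,
                              start_time = 2,
                              max_run = 3L) {
  stopifnot(n_blocks >= 1, block_size %% 3 == 0,
            length(silence_range) == 2, diff(silence_range) >= 0)
  per_cond <- block_size %/% 3L

  with_seed(seed, {
    conds <- character(0)
    for (b in seq_len(n_blocks)) {
      # rejection-sample a block permutation; check runs across the block
      # boundary so the whole session obeys the constraint
      tail_prev <- utils::tail(conds, max_run)
      repeat {
        block <- sample(rep(task_conditions, per_cond))
        if (max_run_length(c(tail_prev, block)) <= max_run) break
      }
      conds <- c(conds, block)
    }
    n <- length(conds)
    silence <- runif(n, silence_range[1], silence_range[2])
    onset <- start_time +
      c(0, cumsum(instruction_duration + silence[-n]))
    sched <- data.frame(
      condition = conds,
      onset_time = onset,
      instruction_duration = instruction_duration,
      silence_duration = silence,
      stringsAsFactors = FALSE
    )
    structure(sched,
              block_size = as.integer(block_size),
              n_blocks = as.integer(n_blocks),
              class = c("instruction_schedule", "data.frame"))
  })
}
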