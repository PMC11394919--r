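#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows distinct n rename if_else
#'   row_number across all_of desc pull count
#' @importFrom tibble tibble as_tibble
#' @importFrom stats p.adjust rbinom rpois rbeta rnbinom runif rnorm median
#'   dbinom phyper pnorm setNames quantile var
NULL

# single chromosome name used by the synthetic genome
SIM_CHROM <- "chrS"

stop_if_not <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg, call = NULL)
  invisible(TRUE)
}

check_prob <- function(x, name, open_low = FALSE) {
  stop_if_not(is.numeric(x) && length(x) == 1L && !is.na(x) &&
                x >= 0 && x <= 1 && (!open_low || x > 0),
              paste0("`", name, "` must be a probability in [0, 1]"))
}

check_count <- function(x, name, min = 1) {
  stop_if_not(is.numeric(x) && length(x) == 1L && !is.na(x) &&
                x >= min && x == floor(x),
              paste0("`", name, "` must be an integer >= ", min))
}

# deterministic sub-seed for a named stage, kept within 32-bit range
stage_seed <- function(seed, stage) {
  offsets <- c(annotation = 11L, depths = 23L, catalogs = 37L,
               counts = 51L, ppi = 67L, ase = 83L)
  ((as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]) %% 2147483647L
}
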