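#' Specify a one-back EEG experimental design
#'
#' Describes a rapid event-related design in which every video condition is
#' shown once per block in pseudo-random order, and a small number of catch
#' events (immediate repeats of a just-shown video, detected by the
#' participant in a one-back task) are inserted per block. The default
#' parameters reproduce the 75-video (39 social, 36 nonsocial), 15-block,
#' 4-catch-events-per-block design: 75 + 2 * 4 = 83 trials per block and
#' 15 * 83 = 1245 trials overall.
#'
#' @param n_videos number of distinct video conditions (default 75).
#' @param n_social how many of the conditions are labelled social (default
#'   39); the remainder are nonsocial.
#' @param n_blocks number of blocks (default 15).
#' @param n_catch_events_per_block catch events inserted per block (default
#'   4). Each catch event contributes two extra presentations of one
#'   already-scheduled condition.
#' @param seed integer seed making the design reproducible.
#'
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_videos = 75L, n_social = 39L, n_blocks = 15L,
                        n_catch_events_per_block = 4L, seed = 1L) {
  n_videos <- stopifnot_scalar_count(n_videos, "n_videos", min = 1L)
  n_social <- stopifnot_scalar_count(n_social, "n_social")
  n_blocks <- stopifnot_scalar_count(n_blocks, "n_blocks")
  n_catch <- stopifnot_scalar_count(n_catch_events_per_block,
                                    "n_catch_events_per_block")
  if (n_social > n_videos) stop("n_social must not exceed n_videos", call. = FALSE)
  if (n_catch > n_videos) {
    stop("invalid design: more catch events than available conditions per block",
         call. = FALSE)
  }
  structure(list(n_videos = n_videos, n_social = n_social, n_blocks = n_blocks,
                 n_catch_events_per_block = n_catch, seed = as.integer(seed)),
            class = "design_spec")
}

#' Generate a pseudo-random trial sequence from a design specification
#'
#' Within each block, all conditions appear exactly once as non-catch trials
#' in a random order. Each catch event then inserts two additional
#' presentations of one randomly chosen condition immediately after that
#' condition's scheduled trial, so the observer experiences consecutive
#' identical videos (the one-back target) and each catch event adds exactly
#' two trials. Catch conditions are sampled without replacement within a
#' block.
#'
#' @param spec a [design_spec()].
#' @return A `trial_sequence`: a data.frame with columns `block`, `trial`
#'   (index within block), `condition` and `is_catch` (logical; `TRUE` for
#'   the two inserted repeat presentations, which carry motor responses and
#'   are excluded from analysis).
#' @export
#'
#' @examples
#' des <- generate_design(design_spec(n_videos = 10, n_blocks = 2,
#'                                    n_catch_events_per_block = 1))
#' table(des$block)  # 12 trials per block
generate_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  with_seed(child_seed(spec$seed, 1L), {
    blocks <- lapply(seq_len(spec$n_blocks), function(b) {
      order <- sample.int(spec$n_videos)
      catch_conds <- if (spec$n_catch_events_per_block > 0L) {
        sample(order, spec$n_catch_events_per_block)
      } else integer(0)
      cond <- integer(0)
      is_catch <- logical(0)
      for (k in order) {
        if (k %in% catch_conds) {
          cond <- c(cond, k, k, k)
          is_catch <- c(is_catch, FALSE, TRUE, TRUE)
        } else {
          cond <- c(cond, k)
          is_catch <- c(is_catch, FALSE)
        }
      }
      data.frame(block = b, trial = seq_along(cond), condition = cond,
                 is_catch = is_catch)
    })
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    class(out) <- c("trial_sequence", "data.frame")
    attr(out, "spec") <- spec
    out
  })
}
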