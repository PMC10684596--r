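#' Build a resolvable alpha-lattice trial design
#'
#' Lays out a replicated multi-environment trial in which each replicate is
#' partitioned into incomplete blocks of `block_size` plots. Every genotype
#' appears exactly once per replicate per season (the design is resolvable),
#' and the genotype-to-block assignment is re-randomized independently for
#' each (season, replicate) pair.
#'
#' @param n_genotypes number of genotypes entered in the trial.
#' @param seasons number of seasons (environments).
#' @param reps number of replicates per season.
#' @param block_size plots per incomplete block within a replicate.
#' @param seed integer seed; the layout is deterministic given the seed.
#' @param genotype_ids optional character vector of genotype labels
#'   (defaults to `G001`, `G002`, ...).
#' @param allow_short_block if `TRUE`, a non-divisible `n_genotypes` is laid
#'   out with one short final block per replicate instead of an error.
#'
#' @return An object of class `trial_design`: a list with the design
#'   parameters, the genotype labels, and `$plots`, a data frame with one row
#'   per field plot (`season`, `rep`, `block`, `plot`, `genotype`).
#' @examples
#' d <- build_design(120, seasons = 2, reps = 2, block_size = 15, seed = 1)
#' nrow(d$plots)   # 480 plot positions
#' @export
build_design <- function(n_genotypes, seasons, reps, block_size, seed,
                         genotype_ids = NULL, allow_short_block = FALSE) {
  stopifnot(n_genotypes >= 1, seasons >= 1, reps >= 1, block_size >= 1)
  if (block_size > n_genotypes)
    stop("`block_size` cannot exceed `n_genotypes`", call. = FALSE)
  if (n_genotypes %% block_size != 0 && !allow_short_block)
    stop(sprintf(
      "n_genotypes (%d) is not divisible by block_size (%d); set allow_short_block = TRUE for a last short block",
      n_genotypes, block_size), call. = FALSE)
  if (is.null(genotype_ids))
    genotype_ids <- sprintf("G%03d", seq_len(n_genotypes))
  if (length(genotype_ids) != n_genotypes || anyDuplicated(genotype_ids))
    stop("`genotype_ids` must be ", n_genotypes, " unique labels", call. = FALSE)

  n_blocks <- ceiling(n_genotypes / block_size)
  block_of <- rep(seq_len(n_blocks), each = block_size, length.out = n_genotypes)

  set.seed(as.integer(seed))
  plots <- vector("list", seasons * reps)
  k <- 0L
  for (s in seq_len(seasons)) {
    for (r in seq_len(reps)) {
      k <- k + 1L
      perm <- sample(genotype_ids)
      plots[[k]] <- data.frame(
        season = s, rep = r, block = block_of,
        plot = seq_len(n_genotypes), genotype = perm,
        stringsAsFactors = FALSE)
    }
  }
  out <- list(
    n_genotypes = n_genotypes, seasons = seasons, reps = reps,
    block_size = block_size, n_blocks = n_blocks,
    genotype_ids = genotype_ids, seed = as.integer(seed),
    plots = do.call(rbind, plots))
  class(out) <- "trial_design"
  out
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf(
    "Alpha-lattice trial design: %d genotypes, %d season(s) x %d rep(s), %d block(s) of up to %d plots per replicate (%d plots total)\n",
    x$n_genotypes, x$seasons, x$reps, x$n_blocks, x$block_size, nrow(x$plots)))
  invisible(x)
}
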