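## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the generator, runs `expr`, and restores the caller's RNG state, so
#' seeded operations are pure functions of their seed and never perturb the
#' session stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Derive a per-stage seed from a master seed
#'
#' Polynomial string hash of the stage name folded into the master seed,
#' reduced modulo 2^31 - 1, so adding a stage never perturbs the seeds of
#' other stages.
#' @noRd
stage_seed <- function(master_seed, stage_name) {
  stopifnot(is.character(stage_name), length(stage_name) == 1L)
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (k in utf8ToInt(stage_name)) h <- (h * 131 + k) %% m
  as.integer((abs(as.numeric(master_seed)) %% m + h) %% m)
}

#' Stop with a consistent error class
#' @noRd
pm_stop <- function(..., class = "plaqmap_error") {
  stop(errorCondition(paste0(...), class = c(class, "plaqmap_error")))
}

pm_validation_error <- function(...) pm_stop(..., class = "plaqmap_validation_error")
pm_format_error <- function(...) pm_stop(..., class = "plaqmap_format_error")

#' Write a data.frame as canonical TSV (header, no quotes, no row names)
#'
#' Canonical formatting makes reader/writer round trips byte-identical.
#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Thin wrapper over [stats::p.adjust()]; kept as a single internal entry
#' point so the adjustment method is changed in one place.
#' @noRd
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
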