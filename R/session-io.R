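#' Write a session to a directory of plain-text files
#'
#' Writes \code{trials.tsv} (per-trial scalars, generative parameters merged
#' in), \code{samples.tsv} (per-sample positions) and \code{config.json}.
#' Both TSV files start with a provenance comment line (\code{#} prefix)
#' recording the seed and a hash of the serialized config.
#'
#' @param session a \code{traj_session}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "traj_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(unclass(session$config), auto_unbox = TRUE,
                               digits = NA)
  writeLines(cfg_json, file.path(dir, "config.json"))
  prov <- sprintf("# trajcomb session; seed=%s; config_sha=%s",
                  session$seed, config_hash(session$config))
  write_prov_tsv <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(prov, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  trials <- merge(session$trials,
                  session$environment[, c("trial", "jump_mean", "jump_sd")],
                  by = "trial")
  trials <- trials[order(trials$trial), ]
  write_prov_tsv(trials, file.path(dir, "trials.tsv"))
  write_prov_tsv(session$samples, file.path(dir, "samples.tsv"))
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir directory containing \code{trials.tsv}, \code{samples.tsv} and
#'   \code{config.json}.
#' @return a \code{traj_session}.
#' @export
read_session <- function(dir) {
  cfg <- jsonlite::fromJSON(file.path(dir, "config.json"))
  config <- do.call(task_config,
                    cfg[setdiff(names(cfg), character(0))])
  trials <- utils::read.delim(file.path(dir, "trials.tsv"), comment.char = "#")
  samples <- utils::read.delim(file.path(dir, "samples.tsv"), comment.char = "#")
  first <- readLines(file.path(dir, "trials.tsv"), n = 1L)
  seed <- sub(".*seed=([^;]+);.*", "\\1", first)
  env <- trials[, c("trial", "mu_gen", "sigma_gen", "jump_mean", "jump_sd")]
  session <- list(config = config,
                  environment = env,
                  trials = trials[, setdiff(names(trials),
                                            c("jump_mean", "jump_sd"))],
                  samples = samples,
                  seed = suppressWarnings(as.integer(seed)))
  class(session) <- "traj_session"
  session
}

# stable short hash of a config (serialization-based, no extra deps)
config_hash <- function(config) {
  raw <- serialize(unclass(config), NULL, version = 2)
  sum_ <- sum(as.integer(raw) * seq_along(raw)) %% 2147483647
  sprintf("%08x", sum_)
}
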