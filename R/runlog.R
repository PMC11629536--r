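# Run-log methods: print / summary / plot for hitl_run objects, lossless JSON
# serialization of the log record, and multi-run comparison reports.

#' @export
print.hitl_run <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<hitl_run> %s | %s acquisition | R = %d rounds%s\n",
              cfg$task, cfg$acquisition, cfg$R,
              if (cfg$no_feedback) " | no-feedback baseline" else ""))
  cat(sprintf("  generation: %d steps x %d proposals per round; AL: L = %d x T = %d\n",
              cfg$n_steps, cfg$P, cfg$L, cfg$T))
  cat(sprintf("  expert calls: %d | fine-tunes: %d\n", x$expert_calls, x$n_finetunes))
  if (!is.null(x$rounds)) {
    cat("  round summary:\n")
    print(x$rounds, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.hitl_run <- function(object, ...) {
  r <- object$rounds
  out <- list(
    config = object$config,
    final_mae = if (!is.null(r)) r$mae_post[nrow(r)] else NA_real_,
    first_mae = if (!is.null(r)) r$mae_post[1L] else NA_real_,
    total_queries = if (!is.null(r)) sum(r$n_queries) else 0L,
    mean_total_last_steps = if (!is.null(object$steps))
      mean(utils::tail(object$steps$mean_total, 10L)) else NA_real_)
  class(out) <- "summary.hitl_run"
  out
}

#' @export
print.summary.hitl_run <- function(x, ...) {
  cat(sprintf("hitl_run summary (%s, %s):\n", x$config$task, x$config$acquisition))
  cat(sprintf("  MAE on top pool molecules: round 1 = %.4f -> round %d = %.4f\n",
              x$first_mae, x$config$R, x$final_mae))
  cat(sprintf("  expert queries: %d | mean total score (last 10 steps): %.3f\n",
              x$total_queries, x$mean_total_last_steps))
  invisible(x)
}

#' @export
plot.hitl_run <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  s <- x$steps
  if (!is.null(s)) {
    idx <- seq_len(nrow(s))
    graphics::plot(idx, s$mean_total, type = "l", xlab = "generation step",
                   ylab = "mean total score", main = "Generator trajectory", ...)
    starts <- which(s$step == 1L)
    graphics::abline(v = idx[starts], lty = 3, col = "grey50")
  }
  r <- x$rounds
  if (!is.null(r)) {
    ylim <- range(c(r$mae_pre, r$mae_post), na.rm = TRUE)
    graphics::plot(r$round, r$mae_pre, type = "b", pch = 1, ylim = ylim,
                   xlab = "round", ylab = "MAE (top pool vs oracle)",
                   main = "Predictor alignment")
    graphics::lines(r$round, r$mae_post, type = "b", pch = 19)
    graphics::legend("topright", c("before fine-tune", "after fine-tune"),
                     pch = c(1, 19), bty = "n")
  }
  invisible(x)
}

# the serializable log record of a run (data, not live model objects)
runlog_record <- function(run) {
  stopifnot(inherits(run, "hitl_run"))
  list(config = run$config,
       steps = run$steps,
       rounds = run$rounds,
       queries = run$queries,
       expert_calls = run$expert_calls,
       n_finetunes = run$n_finetunes)
}

#' Serialize a run log
#'
#' `runlog_json()` renders the run's log record (config echo, step / round /
#' query logs, call counters) as canonical JSON at full numeric precision;
#' `runlog_save()` / `runlog_load()` round-trip it through a file. Two runs
#' with identical configs and seeds produce byte-identical JSON.
#'
#' @param run a `hitl_run`.
#' @return `runlog_json()`: a JSON string.
#' @export
runlog_json <- function(run) {
  as.character(jsonlite::toJSON(runlog_record(run), digits = NA, na = "null",
                                auto_unbox = TRUE, dataframe = "columns",
                                null = "null"))
}

#' @rdname runlog_json
#' @param path file path.
#' @export
runlog_save <- function(run, path) {
  writeLines(runlog_json(run), path)
  invisible(path)
}

#' @rdname runlog_json
#' @export
runlog_load <- function(path) {
  rec <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE), collapse = "\n"),
                            simplifyVector = TRUE)
  for (nm in c("steps", "rounds", "queries"))
    if (!is.null(rec[[nm]])) rec[[nm]] <- as.data.frame(rec[[nm]])
  rec
}

#' Agent checkpointing
#'
#' Saves / restores a [generator_agent()] as JSON (library plus current and
#' prior weight vectors).
#'
#' @param agent a `generator_agent`.
#' @param path file path.
#' @export
agent_save <- function(agent, path) {
  stopifnot(inherits(agent, "generator_agent"))
  writeLines(as.character(jsonlite::toJSON(unclass(agent), digits = NA)), path)
  invisible(path)
}

#' @rdname agent_save
#' @export
agent_load <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE), collapse = "\n"))
  agent <- generator_agent(obj$library)
  agent$weights <- as.numeric(obj$weights)
  agent$prior <- as.numeric(obj$prior)
  agent
}

# configs comparable? (identical echoes up to seeds)
config_comparable <- function(a, b) {
  a$seeds <- NULL; b$seeds <- NULL
  identical(a, b)
}

#' Compare replicate runs
#'
#' Summarizes a list of runs (replicates of one configuration up to seeds):
#' per-round mean and standard deviation of the MAE and the final-step mean
#' total score, plus the combined step trajectories. Refuses to mix
#' incompatible configurations and reports which fields differ.
#'
#' @param runlogs nonempty list of `hitl_run` objects.
#' @return an object of class `hitl_report` with fields `table` (per-round
#'   mean +/- sd) and `trajectories` (stacked step logs).
#' @export
report <- function(runlogs) {
  if (!length(runlogs)) stop_molhitl("need at least one run log")
  stopifnot(all(vapply(runlogs, inherits, logical(1), "hitl_run")))
  base <- runlogs[[1L]]$config
  for (i in seq_along(runlogs)) {
    other <- runlogs[[i]]$config
    if (!config_comparable(base, other)) {
      a <- base; b <- other; a$seeds <- NULL; b$seeds <- NULL
      diff <- names(a)[!mapply(identical, a, b[names(a)])]
      stop_molhitl("incompatible run configs (fields differ: %s)",
                   paste(diff, collapse = ", "))
    }
  }
  rounds <- do.call(rbind, lapply(seq_along(runlogs), function(i)
    cbind(replicate = i, runlogs[[i]]$rounds)))
  agg <- function(v, f) stats::aggregate(v, list(round = rounds$round), f)$x
  table <- data.frame(
    round = sort(unique(rounds$round)),
    mae_mean = agg(rounds$mae_post, mean),
    mae_sd = agg(rounds$mae_post, function(v) if (length(v) > 1) stats::sd(v) else 0),
    pool_mean = agg(rounds$pool_size, mean),
    queries_mean = agg(rounds$n_queries, mean))
  traj <- do.call(rbind, lapply(seq_along(runlogs), function(i)
    cbind(replicate = i, runlogs[[i]]$steps)))
  structure(list(table = table, trajectories = traj,
                 n_replicates = length(runlogs), config = base),
            class = "hitl_report")
}

#' @export
print.hitl_report <- function(x, ...) {
  cat(sprintf("<hitl_report> %d replicate(s), %s acquisition%s\n",
              x$n_replicates, x$config$acquisition,
              if (x$config$no_feedback) " (no-feedback baseline)" else ""))
  print(x$table, row.names = FALSE)
  invisible(x)
}
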