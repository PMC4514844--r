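## Structured-text caches (JSON), trajectory CSV, and configuration files.

.fmt17 <- function(x) sprintf("%.17g", x)

#' Quadrature cache files
#'
#' A cache file is a JSON array of records `{R, N, points[], weights[]}`
#' with values serialized as decimal strings at 17 significant digits
#' (lossless for doubles).
#'
#' @param rules a list of [QuadratureRule-class] objects, or an environment
#'   cache as used by [assemblePropagator()].
#' @param path file path.
#' @return `readQuadratureCache` returns an environment cache keyed by
#'   (R, N), usable as the `cache` argument of [assemblePropagator()].
#' @export
writeQuadratureCache <- function(rules, path) {
  if (is.environment(rules)) rules <- as.list(rules)
  recs <- lapply(unname(rules), function(r) {
    list(R = .fmt17(r@R), N = r@N, points = .fmt17(r@points),
         weights = .fmt17(r@weights))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeQuadratureCache
#' @export
readQuadratureCache <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE)
  cache <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(recs))) {
    R <- as.numeric(recs$R[k])
    N <- as.integer(recs$N[k])
    rule <- new("QuadratureRule", R = R, N = N,
                points = as.numeric(recs$points[[k]]),
                weights = as.numeric(recs$weights[[k]]),
                precisionDigits = NA_integer_)
    cache[[.gdqCacheKey(R, N)]] <- rule
  }
  cache
}

#' Grid cache files
#'
#' JSON object `{R_max, tol, m_max, points[], I_near, I_far}`.
#'
#' @param grid an [InterpolationGrid-class].
#' @param path file path.
#' @export
writeGridCache <- function(grid, path) {
  jsonlite::write_json(
    list(R_max = .fmt17(grid@RMax), tol = .fmt17(grid@tol),
         m_max = grid@mMax, points = .fmt17(grid@points),
         I_near = nNear(grid), I_far = nFar(grid)),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeGridCache
#' @export
readGridCache <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("InterpolationGrid", points = as.numeric(o$points),
      RMax = as.numeric(o$R_max), tol = as.numeric(o$tol),
      mMax = as.integer(o$m_max))
}

#' Propagation-matrix cache files
#'
#' JSON object with the (i, j, x) triplets of W, the source vector, the
#' orders, and the grid.
#'
#' @param P a [PropagationMatrix-class].
#' @param path file path.
#' @export
writeMatrixCache <- function(P, path) {
  tr <- Matrix::summary(P@W)
  jsonlite::write_json(
    list(N = P@N, NF = P@NF, i = tr$i, j = tr$j, x = .fmt17(tr$x),
         s = .fmt17(P@s),
         grid = list(R_max = .fmt17(P@grid@RMax), tol = .fmt17(P@grid@tol),
                     m_max = P@grid@mMax, points = .fmt17(P@grid@points))),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeMatrixCache
#' @export
readMatrixCache <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- new("InterpolationGrid", points = as.numeric(o$grid$points),
              RMax = as.numeric(o$grid$R_max), tol = as.numeric(o$grid$tol),
              mMax = as.integer(o$grid$m_max))
  I <- length(grid@points)
  W <- Matrix::sparseMatrix(i = as.integer(o$i), j = as.integer(o$j),
                            x = as.numeric(o$x), dims = c(I, I))
  new("PropagationMatrix", W = methods::as(W, "CsparseMatrix"),
      s = as.numeric(o$s), grid = grid, N = as.integer(o$N),
      NF = as.integer(o$NF))
}

#' Write a trajectory as CSV
#'
#' One row per recorded step with columns `step`, `t_seconds`, `chi`, then
#' rho at each grid point (columns `rho_R<i>`).
#'
#' @param traj a [Trajectory-class].
#' @param path file path.
#' @param dt seconds per step (for the `t_seconds` column); NA if unknown.
#' @export
writeTrajectory <- function(traj, path, dt = NA_real_) {
  steps <- traj@recSteps
  df <- data.frame(step = steps, t_seconds = steps * dt,
                   chi = traj@state@chi[steps])
  rho <- as.data.frame(traj@recorded)
  names(rho) <- sprintf("rho_R%d", seq_len(ncol(rho)))
  write.csv(cbind(df, rho), path, row.names = FALSE)
  invisible(path)
}

#' Write an error trace as CSV
#'
#' Columns `step`, `eps`.
#'
#' @param report an [ErrorReport-class].
#' @param path file path.
#' @export
writeErrorTrace <- function(report, path) {
  write.csv(epsTrace(report), path, row.names = FALSE)
  invisible(path)
}

## ---- configuration --------------------------------------------------------

#' Read a run-configuration file
#'
#' The format is TOML-like sectioned key/value text:
#' ```
#' [physical]
#' D_m2_per_s = 1e-9
#' dt_s = 1e-7
#' j_per_s = 1e7
#' c0_M = 0
#' geometry = full
#' [algorithm]
#' N = 10
#' NF = 8
#' I_near = 25
#' I_far = 90
#' R_max = 5148
#' precision_digits = 120
#' [source]
#' kind = always_on
#' [output]
#' dir = out
#' record_every = 100
#' ```
#' Physical keys carry explicit unit suffixes.  `[source] kind` is one of
#' `always_on`, `schedule` (with `schedule = 1,0,1,...`), `bernoulli`
#' (with `p_on`, `seed`).  An optional `[reaction]` section has
#' `k_on_per_M_s`, `k_off_per_s`, `b_free_M`, `B_bound_M`.  Missing or
#' malformed required fields raise errors naming the field.
#'
#' @param path path to the configuration file.
#' @return a nested list of sections.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      cfg[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) stop("config entry outside any [section]: ", ln)
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      num <- suppressWarnings(as.numeric(strsplit(val, ",", fixed = TRUE)[[1]]))
      cfg[[section]][[key]] <- if (!anyNA(num)) num else val
    } else {
      stop("malformed config line: ", ln)
    }
  }
  .validateConfig(cfg)
  cfg
}

.need <- function(cfg, section, field) {
  v <- cfg[[section]][[field]]
  if (is.null(v))
    stop("config validation: missing required field [", section, "] ", field)
  v
}

.validateConfig <- function(cfg) {
  for (f in c("D_m2_per_s", "dt_s", "j_per_s")) .need(cfg, "physical", f)
  for (f in c("N", "NF", "I_near", "I_far", "R_max")) .need(cfg, "algorithm", f)
  kind <- .need(cfg, "source", "kind")
  if (!kind %in% c("always_on", "schedule", "bernoulli"))
    stop("config validation: [source] kind must be always_on, schedule or ",
         "bernoulli (feedback sources are programmatic), got: ", kind)
  if (kind == "bernoulli") {
    .need(cfg, "source", "p_on")
    .need(cfg, "source", "seed")
  }
  if (kind == "schedule") .need(cfg, "source", "schedule")
  invisible(cfg)
}

.configPhysical <- function(cfg) {
  physicalParams(D = .need(cfg, "physical", "D_m2_per_s"),
                 dt = .need(cfg, "physical", "dt_s"),
                 j = .need(cfg, "physical", "j_per_s"),
                 c0 = if (!is.null(cfg$physical$c0_M)) cfg$physical$c0_M else 0,
                 geometry = if (!is.null(cfg$physical$geometry))
                   cfg$physical$geometry else "full")
}

.configSource <- function(cfg) {
  switch(cfg$source$kind,
    always_on = sourceAlwaysOn(),
    schedule = sourceSchedule(cfg$source$schedule),
    bernoulli = sourceBernoulli(cfg$source$p_on))
}

.configReaction <- function(cfg) {
  if (is.null(cfg$reaction)) return(NULL)
  new("ReactionParams",
      kOn = .need(cfg, "reaction", "k_on_per_M_s"),
      kOff = .need(cfg, "reaction", "k_off_per_s"),
      bFree = .need(cfg, "reaction", "b_free_M"),
      BBound = .need(cfg, "reaction", "B_bound_M"))
}
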