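#' Read and write XYZ trajectories
#'
#' Conformations are serialized as standard multi-frame XYZ: for each
#' frame a vertex-count line, a free-form comment line, then one
#' `element x y z` row per vertex. The writer fixes the element field to
#' `"C"`, formats coordinates with 9 significant digits (so a write/read
#' round trip is exact at that precision), and stores frame metadata
#' (frame index, coupling `u`, seed) in the comment line. The reader
#' tolerates arbitrary element labels.
#'
#' @param path File path.
#' @param frames A list of conformations / vertex matrices, or a
#'   `"trajectory"`.
#' @param u,seed Optional metadata recorded in each frame's comment line.
#' @param b Bond length attached to the conformations on reading (`NA` to
#'   return plain matrices without bond validation).
#' @return `read_xyz()` returns a list of [conformation()]s (or plain
#'   matrices when `b = NA`), with each frame's comment line attached as
#'   attribute `"comment"`; `write_xyz()` returns `path` invisibly.
#' @export
write_xyz <- function(frames, path, u = NULL, seed = NULL) {
  if (inherits(frames, "trajectory")) {
    if (is.null(u)) u <- frames$params$u
    if (is.null(seed)) seed <- frames$seed
    frames <- frames$frames
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    v <- unclass(as.matrix(frames[[i]]))
    meta <- c(sprintf("frame=%d", i),
              if (!is.null(u)) sprintf("u=%.9g", u),
              if (!is.null(seed)) sprintf("seed=%d", as.integer(seed)))
    writeLines(c(as.character(nrow(v)), paste(meta, collapse = " ")), con)
    writeLines(sprintf("C %.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path, b = 1) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i])) {
      stop(sprintf("%s:%d: expected a vertex count, got '%s'", path, i,
                   lines[i]))
    }
    n <- as.integer(lines[i])
    if (i + 1L + n > length(lines)) {
      stop(sprintf("%s:%d: frame announces %d vertices but file ends early",
                   path, i, n))
    }
    comment <- lines[i + 1L]
    rows <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(rows), "\\s+")
    bad <- which(lengths(parts) < 4L)
    if (length(bad) > 0L) {
      stop(sprintf("%s:%d: malformed vertex row '%s'", path,
                   i + 1L + bad[1L], rows[bad[1L]]))
    }
    v <- matrix(as.numeric(unlist(lapply(parts, function(p) p[2:4]))),
                ncol = 3L, byrow = TRUE)
    if (anyNA(v)) {
      stop(sprintf("%s: non-numeric coordinate in frame starting line %d",
                   path, i))
    }
    # tolerance matches the writer's 9-significant-digit formatting
    fr <- if (is.na(b)) v else conformation(v, b = b, tol = 1e-6)
    attr(fr, "comment") <- comment
    frames[[length(frames) + 1L]] <- fr
    i <- i + 2L + n
  }
  frames
}

#' Write per-frame observables as CSV
#'
#' One row per frame with the chain-mean torsion and the chiral energy;
#' run-level summaries (ensemble torsion and chiral-energy variance, with
#' standard errors) are included as comment-free trailing columns of a
#' separate one-row summary file when `summary_path` is given.
#'
#' @param trajectory A `"trajectory"`.
#' @param path Output CSV path.
#' @param summary_path Optional path for the run-level summary CSV.
#' @return `path`, invisibly.
#' @export
write_observables <- function(trajectory, path, summary_path = NULL) {
  tm <- vapply(trajectory$frames,
               function(f) discrete_torsion(f)$tau_mean, numeric(1))
  df <- data.frame(frame = seq_along(tm), tau_mean = tm,
                   E_bend = trajectory$energies$E_bend,
                   E_chiral = trajectory$energies$E_chiral)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(summary_path)) {
    et <- ensemble_torsion(trajectory)
    cv <- chiral_variance(trajectory)
    sm <- data.frame(n_frames = length(tm), tau = et$tau, se_tau = et$se,
                     C_c = cv$C_c, se_Cc = cv$se_Cc,
                     u = trajectory$params$u, N = trajectory$params$N,
                     seed = trajectory$seed)
    utils::write.csv(sm, summary_path, row.names = FALSE)
  }
  invisible(path)
}

#' Write a knot census as JSON
#'
#' Schema: `{u: {P_k, se_P_k, n_total, n_knotted, types: {label: {share,
#' P_rk, n, ...}}}}`.
#'
#' @param census A `"knot_census"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_census_json <- function(census, path) {
  jsonlite::write_json(unclass(census), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
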