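#' Screen for tightly braided conformations
#'
#' Flags conformations in which at least two segments that are far apart
#' along the contour (separation greater than `d` segments) have centers
#' closer than a cutoff `r_min`. Such conformations contain tightly packed
#' interwoven helical sections ("braids") whose winding inherits the
#' molecular helical sense and biases knot handedness; removing them
#' isolates that mechanism.
#'
#' @param conf A [conformation()].
#' @param r_min Cutoff distance between segment centers (units of `b`,
#'   default 1.5).
#' @param d Contour-separation threshold in segments.
#' @return `TRUE` if the conformation should be dropped.
#' @export
braid_screen <- function(conf, r_min = 1.5, d = 10L) {
  stopifnot(r_min > 0, d >= 0)
  ctr <- segment_centers(conf)
  n <- nrow(ctr)
  lim2 <- r_min^2
  if (d + 1L > n - 1L) return(FALSE)
  for (k in (d + 1L):(n - 1L)) {
    i <- seq_len(n - k)
    d2 <- rowSums((ctr[i + k, , drop = FALSE] - ctr[i, , drop = FALSE])^2)
    if (any(d2 < lim2)) return(TRUE)
  }
  FALSE
}

#' Census of knot types and handedness
#'
#' Aggregates per-frame knot labels into the knotting probability `P_k`,
#' the per-type occurrence probability normalized by the total knotting
#' probability (`P_k,norm`), and the probability `P_rk` that a knot of a
#' given type is right-handed, with binomial standard errors
#' `sqrt(p (1 - p) / n)` throughout. When labels from several coupling
#' strengths are mixed, pass `u` per frame and the census is computed per
#' `u` value.
#'
#' Indeterminate labels are counted in `n_total` but excluded from the
#' knotted count and from all type shares; the number excluded is reported
#' in `n_indeterminate`.
#'
#' @param labels A data frame as from [classify_frames()] (columns `type`,
#'   `handedness`, optionally `indeterminate`).
#' @param u Either a single coupling value for all frames or a vector with
#'   one entry per frame.
#' @return An object of class `"knot_census"`: a list keyed by `u` value;
#'   each entry has `n_total`, `n_knotted`, `n_indeterminate`, `P_k`,
#'   `se_P_k`, and `types`, a per-type list with `n`, `n_right`, `n_left`,
#'   `share` (`P_k,norm`), `se_share`, `P_rk`, `se_P_rk` (the latter two
#'   `NA` for achiral or unobserved types).
#' @export
knot_census <- function(labels, u = 0) {
  stopifnot(is.data.frame(labels), all(c("type", "handedness") %in%
                                         names(labels)))
  if (length(u) == 1L) u <- rep(u, nrow(labels))
  stopifnot(length(u) == nrow(labels))
  ind <- if ("indeterminate" %in% names(labels)) labels$indeterminate else
    rep(FALSE, nrow(labels))
  out <- list()
  for (uv in sort(unique(u))) {
    sel <- u == uv
    lab <- labels[sel, , drop = FALSE]
    ii <- ind[sel]
    n_total <- nrow(lab)
    knotted <- !ii & lab$type != "unknot"
    n_knot <- sum(knotted)
    P_k <- n_knot / n_total
    types <- list()
    for (ty in sort(unique(lab$type[knotted]))) {
      tsel <- knotted & lab$type == ty
      n_ty <- sum(tsel)
      n_r <- sum(tsel & lab$handedness == "right")
      n_l <- sum(tsel & lab$handedness == "left")
      share <- if (n_knot > 0L) n_ty / n_knot else NA_real_
      se_share <- if (n_knot > 0L) sqrt(share * (1 - share) / n_knot) else
        NA_real_
      nc <- n_r + n_l
      P_rk <- if (nc > 0L) n_r / nc else NA_real_
      se_P_rk <- if (nc > 0L) sqrt(P_rk * (1 - P_rk) / nc) else NA_real_
      types[[ty]] <- list(n = n_ty, n_right = n_r, n_left = n_l,
                          share = share, se_share = se_share,
                          P_rk = P_rk, se_P_rk = se_P_rk)
    }
    out[[format_u(uv)]] <- list(
      u = uv, n_total = n_total, n_knotted = n_knot,
      n_indeterminate = sum(ii),
      P_k = P_k, se_P_k = sqrt(P_k * (1 - P_k) / n_total),
      types = types)
  }
  structure(out, class = "knot_census")
}

format_u <- function(u) formatC(u, format = "g")

#' @export
print.knot_census <- function(x, ...) {
  for (entry in x) {
    cat(sprintf("u = %g: %d frames, %d knotted (P_k = %.4f +- %.4f)",
                entry$u, entry$n_total, entry$n_knotted, entry$P_k,
                entry$se_P_k))
    if (entry$n_indeterminate > 0L) {
      cat(sprintf(", %d indeterminate", entry$n_indeterminate))
    }
    cat("\n")
    for (ty in names(entry$types)) {
      t <- entry$types[[ty]]
      cat(sprintf("  %-6s n = %4d  share = %.3f", ty, t$n, t$share))
      if (!is.na(t$P_rk)) {
        cat(sprintf("  P_rk = %.3f +- %.3f", t$P_rk, t$se_P_rk))
      }
      cat("\n")
    }
  }
  invisible(x)
}

#' Mirror relabeling of knot labels
#'
#' Swaps right and left handedness on every frame, as reflecting every
#' conformation would. Under this relabeling `P_rk` maps to `1 - P_rk`
#' while `P_k` and the type shares are unchanged.
#'
#' @param labels A data frame as from [classify_frames()].
#' @return The relabeled data frame.
#' @export
mirror_labels <- function(labels) {
  h <- labels$handedness
  labels$handedness <- ifelse(h == "right", "left",
                              ifelse(h == "left", "right", h))
  labels
}

#' Handedness-bias comparison before and after braid screening
#'
#' Tabulates, per coupling value and knot type, the probability of a
#' right-handed knot in the full census and in the screened census, and
#' the deviation of each from the racemic value 0.5.
#'
#' @param census Census of all knotted frames ([knot_census()]).
#' @param screened_census Census after removing braided conformations.
#' @return A data frame with columns `u`, `type`, `P_rk`, `se`,
#'   `P_rk_screened`, `se_screened`, `dev`, `dev_screened`.
#' @export
handedness_bias_report <- function(census, screened_census) {
  rows <- list()
  for (key in names(census)) {
    entry <- census[[key]]
    scr <- screened_census[[key]]
    for (ty in names(entry$types)) {
      t <- entry$types[[ty]]
      s <- if (!is.null(scr)) scr$types[[ty]] else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        u = entry$u, type = ty,
        P_rk = t$P_rk, se = t$se_P_rk,
        P_rk_screened = if (!is.null(s)) s$P_rk else NA_real_,
        se_screened = if (!is.null(s)) s$se_P_rk else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$dev <- abs(out$P_rk - 0.5)
  out$dev_screened <- abs(out$P_rk_screened - 0.5)
  out
}

#' Apply the braid screen to classified frames
#'
#' Drops knotted frames containing a nonlocal contact (the screen is
#' applied to knotted conformations only, unknotted frames pass through)
#' and returns the surviving subset of the label table.
#'
#' @param labels A data frame from [classify_frames()].
#' @param frames The corresponding list of conformations (or a
#'   `"trajectory"`).
#' @inheritParams braid_screen
#' @return The filtered label data frame (attribute `n_dropped` records
#'   how many knotted frames were removed).
#' @export
screen_labels <- function(labels, frames, r_min = 1.5, d = 10L) {
  if (inherits(frames, "trajectory")) frames <- frames$frames
  stopifnot(nrow(labels) == length(frames))
  knotted <- labels$type != "unknot"
  drop <- logical(nrow(labels))
  for (i in which(knotted)) {
    drop[i] <- braid_screen(frames[[i]], r_min = r_min, d = d)
  }
  out <- labels[!drop, , drop = FALSE]
  attr(out, "n_dropped") <- sum(drop)
  out
}
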