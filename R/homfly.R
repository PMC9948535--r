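# Exact two-variable integer Laurent polynomials and the HOMFLY skein
# engine. The skein convention used throughout is
#     l * P(L+) + l^-1 * P(L-) + m * P(L0) = 0,
# with P(unknot) = 1, so a k-component unlink has P = delta^(k-1) with
# delta = -(l + l^-1) / m. Under this convention the mirror image of a
# knot maps l <-> l^-1.

# ---- Laurent polynomial arithmetic -------------------------------------
# representation: numeric matrix with columns (l, m, coef), canonical form
# sorted by (l, m) with zero coefficients dropped. Coefficients are exact
# integers stored as doubles.

lp_canon <- function(p) {
  if (nrow(p) == 0L) return(lp_zero())
  key <- paste(p[, 1L], p[, 2L])
  coef <- tapply(p[, 3L], key, sum)
  expo <- do.call(rbind, strsplit(names(coef), " ", fixed = TRUE))
  out <- cbind(as.numeric(expo[, 1L]), as.numeric(expo[, 2L]),
               as.numeric(coef))
  out <- out[out[, 3L] != 0, , drop = FALSE]
  out <- out[order(out[, 1L], out[, 2L]), , drop = FALSE]
  colnames(out) <- c("l", "m", "coef")
  out
}

lp_zero <- function() {
  matrix(numeric(0), 0L, 3L, dimnames = list(NULL, c("l", "m", "coef")))
}

lp_mono <- function(l = 0, m = 0, coef = 1) {
  matrix(c(l, m, coef), 1L, 3L, dimnames = list(NULL, c("l", "m", "coef")))
}

lp_one <- function() lp_mono(0, 0, 1)

lp_add <- function(a, b) lp_canon(rbind(a, b))

lp_mul <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(lp_zero())
  ia <- rep(seq_len(nrow(a)), each = nrow(b))
  ib <- rep(seq_len(nrow(b)), times = nrow(a))
  lp_canon(cbind(a[ia, 1L] + b[ib, 1L], a[ia, 2L] + b[ib, 2L],
                 a[ia, 3L] * b[ib, 3L]))
}

lp_equal <- function(a, b) {
  isTRUE(all.equal(lp_canon(a), lp_canon(b), check.attributes = FALSE))
}

# mirror image: l <-> l^-1
lp_mirror <- function(p) {
  if (nrow(p) == 0L) return(p)
  p[, 1L] <- -p[, 1L]
  lp_canon(p)
}

lp_eval <- function(p, l, m) {
  if (nrow(p) == 0L) return(0 + 0i)
  sum(p[, 3L] * l^p[, 1L] * m^p[, 2L])
}

lp_delta <- function() rbind(lp_mono(1, -1, -1), lp_mono(-1, -1, -1))

lp_delta_pow <- function(k) {
  out <- lp_one()
  if (k > 0L) for (i in seq_len(k)) out <- lp_mul(out, lp_delta())
  out
}

lp_key <- function(p) paste(p[, 1L], p[, 2L], p[, 3L], collapse = ";")

#' Compare and transform HOMFLY polynomials
#'
#' `homfly_equal()` tests structural equality of two polynomials in
#' canonical form; `homfly_mirror()` returns the polynomial of the mirror
#' image (`l` replaced by `l^-1`).
#'
#' @param a,b,p Polynomials as returned by [homfly()].
#' @return `homfly_equal()` a logical; `homfly_mirror()` a polynomial.
#' @export
homfly_equal <- function(a, b) lp_equal(a, b)

#' @rdname homfly_equal
#' @export
homfly_mirror <- function(p) lp_mirror(p)

#' Format a HOMFLY polynomial as a readable string
#'
#' @param p A polynomial as returned by [homfly()].
#' @return A single string such as `"-l^-4 - 2 l^-2 + l^-2 m^2"`.
#' @export
homfly_format <- function(p) {
  p <- lp_canon(p)
  if (nrow(p) == 0L) return("0")
  term <- function(l, m, c) {
    mono <- c(
      if (l != 0) paste0("l^", l),
      if (m != 0) paste0("m^", m)
    )
    co <- if (abs(c) != 1 || length(mono) == 0L) as.character(abs(c)) else
      NULL
    paste0(if (c < 0) "- " else "+ ", paste(c(co, mono), collapse = " "))
  }
  s <- paste(mapply(term, p[, 1L], p[, 2L], p[, 3L]), collapse = " ")
  sub("^\\+ ", "", s)
}

# ---- combinatorial diagram state ---------------------------------------
# A state is a list(comps, sign): comps is a list of components, each a
# list(cr = integer passage crossing ids, over = logical); sign is an
# integer vector indexed by crossing id. Every crossing id occurs exactly
# twice across all passages.

st_from_diagram <- function(dg) {
  comps <- if (!is.null(dg$components)) dg$components else
    list(list(cr = dg$passages, over = dg$over))
  list(comps = comps, sign = as.integer(dg$sign))
}

st_n_passages <- function(st) {
  sum(vapply(st$comps, function(cp) length(cp$cr), integer(1)))
}

# first crossing (in traversal order) whose first passage is under;
# NULL if the diagram is descending
st_find_bad <- function(st) {
  seen <- integer(0)
  for (ci in seq_along(st$comps)) {
    cp <- st$comps[[ci]]
    for (pi in seq_along(cp$cr)) {
      c <- cp$cr[pi]
      if (!(c %in% seen)) {
        if (!cp$over[pi]) return(c)
        seen <- c(seen, c)
      }
    }
  }
  NULL
}

st_switch <- function(st, c) {
  for (ci in seq_along(st$comps)) {
    idx <- which(st$comps[[ci]]$cr == c)
    if (length(idx) > 0L) {
      st$comps[[ci]]$over[idx] <- !st$comps[[ci]]$over[idx]
    }
  }
  st$sign[c] <- -st$sign[c]
  st
}

# oriented smoothing: remove crossing c, reconnecting the strands
st_smooth <- function(st, c) {
  loc <- which(vapply(st$comps, function(cp) c %in% cp$cr, logical(1)))
  if (length(loc) == 1L) {
    cp <- st$comps[[loc]]
    pos <- which(cp$cr == c)
    p <- pos[1L]; q <- pos[2L]
    seg1 <- seq2(p + 1L, q - 1L)
    seg2 <- c(seq2(q + 1L, length(cp$cr)), seq2(1L, p - 1L))
    st$comps[[loc]] <- list(cr = cp$cr[seg1], over = cp$over[seg1])
    st$comps[[length(st$comps) + 1L]] <-
      list(cr = cp$cr[seg2], over = cp$over[seg2])
  } else {
    a <- st$comps[[loc[1L]]]
    b <- st$comps[[loc[2L]]]
    p <- which(a$cr == c)
    q <- which(b$cr == c)
    ib <- c(seq2(q + 1L, length(b$cr)), seq2(1L, q - 1L))
    ia <- c(seq2(p + 1L, length(a$cr)), seq2(1L, p - 1L))
    merged <- list(cr = c(a$cr[integer(0)], b$cr[ib], a$cr[ia]),
                   over = c(b$over[ib], a$over[ia]))
    st$comps[[loc[1L]]] <- merged
    st$comps[[loc[2L]]] <- NULL
  }
  st
}

seq2 <- function(from, to) if (from > to) integer(0) else from:to

# Reidemeister I and II reductions; they leave the HOMFLY invariant and
# shrink the passage count, which keeps the skein tree small.
st_simplify <- function(st) {
  repeat {
    changed <- FALSE
    # R1: a crossing whose two passages are cyclically consecutive
    for (ci in seq_along(st$comps)) {
      cp <- st$comps[[ci]]
      len <- length(cp$cr)
      if (len < 2L) next
      nxt <- c(seq2(2L, len), 1L)
      hit <- which(cp$cr == cp$cr[nxt])
      if (length(hit) > 0L) {
        p <- hit[1L]
        drop <- c(p, nxt[p])
        st$comps[[ci]] <- list(cr = cp$cr[-drop], over = cp$over[-drop])
        changed <- TRUE
        break
      }
    }
    if (changed) next
    # R2: two crossings adjacent on two strands, one strand over at both,
    # the other under at both
    pairs <- list()
    for (ci in seq_along(st$comps)) {
      cp <- st$comps[[ci]]
      len <- length(cp$cr)
      if (len < 2L) next
      nxt <- c(seq2(2L, len), 1L)
      for (p in seq_len(len)) {
        q <- nxt[p]
        if (cp$cr[p] == cp$cr[q]) next
        if (cp$over[p] != cp$over[q]) next
        key <- paste(min(cp$cr[p], cp$cr[q]), max(cp$cr[p], cp$cr[q]))
        pairs[[length(pairs) + 1L]] <-
          list(key = key, comp = ci, pos = c(p, q), over = cp$over[p],
               cr = c(cp$cr[p], cp$cr[q]))
      }
    }
    if (length(pairs) > 1L) {
      keys <- vapply(pairs, `[[`, character(1), "key")
      for (a in seq_along(pairs)) {
        match_b <- which(keys == keys[a])
        for (b in match_b) {
          if (b <= a) next
          pa <- pairs[[a]]; pb <- pairs[[b]]
          if (pa$over == pb$over) next
          if (pa$comp == pb$comp &&
              length(intersect(pa$pos, pb$pos)) > 0L) next
          st <- st_drop_passages(st, list(pa, pb))
          changed <- TRUE
          break
        }
        if (changed) break
      }
    }
    if (!changed) break
  }
  st
}

st_drop_passages <- function(st, pairlist) {
  drops <- list()
  for (pr in pairlist) {
    ci <- as.character(pr$comp)
    drops[[ci]] <- c(drops[[ci]], pr$pos)
  }
  for (ci in names(drops)) {
    i <- as.integer(ci)
    cp <- st$comps[[i]]
    keep <- setdiff(seq_along(cp$cr), drops[[ci]])
    st$comps[[i]] <- list(cr = cp$cr[keep], over = cp$over[keep])
  }
  st
}

st_key <- function(st) {
  relab <- integer(0)
  out <- character(length(st$comps))
  for (ci in seq_along(st$comps)) {
    cp <- st$comps[[ci]]
    ids <- integer(length(cp$cr))
    for (pi in seq_along(cp$cr)) {
      c <- cp$cr[pi]
      k <- match(c, relab)
      if (is.na(k)) {
        relab <- c(relab, c)
        k <- length(relab)
      }
      ids[pi] <- k
    }
    out[ci] <- paste(ids, ifelse(cp$over, "o", "u"), collapse = " ")
  }
  paste(paste(out, collapse = "|"),
        paste(st$sign[relab], collapse = ","), sep = "#")
}

st_homfly <- function(st, memo) {
  st <- st_simplify(st)
  if (st_n_passages(st) == 0L) {
    return(lp_delta_pow(length(st$comps) - 1L))
  }
  key <- st_key(st)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  bad <- st_find_bad(st)
  if (is.null(bad)) {
    res <- lp_delta_pow(length(st$comps) - 1L)
  } else {
    s <- st$sign[bad]
    p_sw <- st_homfly(st_switch(st, bad), memo)
    p_sm <- st_homfly(st_smooth(st, bad), memo)
    res <- if (s > 0L) {
      lp_add(lp_mul(lp_mono(-2, 0, -1), p_sw),
             lp_mul(lp_mono(-1, 1, -1), p_sm))
    } else {
      lp_add(lp_mul(lp_mono(2, 0, -1), p_sw),
             lp_mul(lp_mono(1, 1, -1), p_sm))
    }
  }
  memo[[key]] <- res
  res
}

#' HOMFLY polynomial of a knot diagram
#'
#' Computes the HOMFLY invariant by skein recursion in the convention
#' `l P(L+) + l^-1 P(L-) + m P(L0) = 0` with `P(unknot) = 1`. The engine
#' applies Reidemeister I/II reductions at every node of the skein tree and
#' memoizes on a canonical diagram code; coefficients are exact integers.
#' The mirror image of a diagram has the polynomial with `l` replaced by
#' `l^-1`.
#'
#' @param diagram A `"knot_diagram"` from [project_diagram()] (or a braid
#'   diagram from [braid_diagram()]).
#' @param cap Maximum number of crossings the engine accepts after
#'   Reidemeister simplification; beyond it the computation aborts with an
#'   error rather than risking an intractable skein tree.
#' @return A polynomial: numeric matrix with columns `l`, `m`, `coef` in
#'   canonical sorted form, suitable for structural equality comparison.
#' @export
homfly <- function(diagram, cap = 16L) {
  st <- st_simplify(st_from_diagram(diagram))
  ncr <- st_n_passages(st) / 2L
  if (ncr > cap) {
    stop(sprintf("diagram has %d crossings after reduction (cap %d)",
                 ncr, cap))
  }
  memo <- new.env(parent = emptyenv())
  st_homfly(st, memo)
}

# ---- independent brute-force skein-tree evaluator ----------------------
# Plain recursion on the raw diagram: no simplification, no memoization,
# and the *last* non-descending crossing is resolved first. Used as an
# oracle against the optimized engine.

#' Brute-force skein-tree evaluation of the HOMFLY polynomial
#'
#' A deliberately simple evaluator used to cross-check [homfly()]: it
#' resolves the skein tree exhaustively without Reidemeister reduction or
#' memoization. Exponential in the crossing number; intended for small
#' reference diagrams.
#'
#' @inheritParams homfly
#' @return A polynomial in the same representation as [homfly()].
#' @export
homfly_bruteforce <- function(diagram) {
  bf_rec(st_from_diagram(diagram))
}

bf_rec <- function(st) {
  # find all crossings whose first passage is an underpass; take the last
  seen <- integer(0)
  bad <- integer(0)
  for (cp in st$comps) {
    for (pi in seq_along(cp$cr)) {
      c <- cp$cr[pi]
      if (!(c %in% seen)) {
        seen <- c(seen, c)
        if (!cp$over[pi]) bad <- c(bad, c)
      }
    }
  }
  if (length(bad) == 0L) {
    k <- length(st$comps)
    out <- lp_one()
    if (k > 1L) for (i in seq_len(k - 1L)) out <- lp_mul(out, lp_delta())
    return(out)
  }
  c <- bad[length(bad)]
  s <- st$sign[c]
  p_sw <- bf_rec(st_switch(st, c))
  p_sm <- bf_rec(st_smooth(st, c))
  if (s > 0L) {
    lp_add(lp_mul(lp_mono(-2, 0, -1), p_sw),
           lp_mul(lp_mono(-1, 1, -1), p_sm))
  } else {
    lp_add(lp_mul(lp_mono(2, 0, -1), p_sw),
           lp_mul(lp_mono(1, 1, -1), p_sm))
  }
}

#' Knot determinant from a HOMFLY polynomial
#'
#' Evaluates the Alexander specialization of the polynomial at `t = -1`
#' and returns its magnitude. The determinant distinguishes the knots
#' handled here (unknot 1, trefoil 3, figure-eight 5, 5_1 5, 5_2 7) and is
#' used as an internal consistency check on reference diagrams.
#'
#' @param p A polynomial from [homfly()].
#' @return A non-negative number.
#' @export
knot_determinant <- function(p) {
  val <- lp_eval(p, l = 1i, m = -2 + 0i)
  round(Mod(val), 6)
}
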