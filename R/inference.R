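#' Dual topology of a restricted tissue network
#'
#' The tension network dual to a cell network has one node per retained cell,
#' one edge per interior junction between two retained cells, and one
#' triangle per three-fold vertex whose three cells are all retained. At
#' mechanical equilibrium this dual is a triangulation whose edges are
#' perpendicular to the corresponding cell edges and whose edge lengths are
#' the junctional tensions.
#'
#' @param network a `tissue_network` passed through [restrict_threefold()]
#'   (applied automatically when missing).
#' @return list of class `dual_topology`: `cells` (retained cell ids),
#'   `edges` (data.frame `junction_id`, `cell_a`, `cell_b`), `triangles`
#'   (data.frame `vertex_id`, `cell_1`, `cell_2`, `cell_3`).
#' @export
build_dual_topology <- function(network) {
  if (is.null(network$junctions$retained)) network <- restrict_threefold(network)
  jn <- network$junctions[network$junctions$retained, , drop = FALSE]
  if (nrow(jn) == 0) stop("restricted network has no interior junction")
  cells <- sort(unique(c(jn$cell_a, jn$cell_b)))

  # triangles from three-fold vertices whose three incident junctions are kept
  tri <- list()
  vids <- network$vertices$id[network$vertices$degree == 3]
  for (v in vids) {
    inc <- jn[jn$v1 == v | jn$v2 == v, , drop = FALSE]
    if (nrow(inc) != 3) next
    cc <- sort(unique(c(inc$cell_a, inc$cell_b)))
    if (length(cc) != 3) next
    tri[[length(tri) + 1]] <- data.frame(vertex_id = v, cell_1 = cc[1],
                                         cell_2 = cc[2], cell_3 = cc[3])
  }
  triangles <- if (length(tri)) do.call(rbind, tri) else
    data.frame(vertex_id = integer(0), cell_1 = integer(0),
               cell_2 = integer(0), cell_3 = integer(0))
  structure(list(cells = cells,
                 edges = data.frame(junction_id = jn$id,
                                    cell_a = jn$cell_a, cell_b = jn$cell_b),
                 triangles = triangles),
            class = "dual_topology")
}

#' Infer relative junctional tensions by variational force inference
#'
#' Fits a tension triangulation perpendicular to the cell network: one node
#' `Q_a` per retained cell, one dual edge per interior junction, minimising
#'
#' \deqn{\Omega = \tfrac12 \sum_{<a,b>} [(Q_a - Q_b) \cdot r_{ij}]^2
#'   - \tfrac{\Lambda}{2} \sum_{<a,b>} |Q_a - Q_b|^2,}
#'
#' where `r_ij` is the end-to-end chord of the junction shared by cells `a`
#' and `b`. Stationarity is the generalized eigenproblem `A q = Lambda B q`
#' over the stacked Q-coordinates; both quadratic forms annihilate global
#' translations of Q, which are deflated exactly (the Q-centroid is pinned at
#' the origin), and the solution is the generalized eigenvector of the
#' smallest remaining eigenvalue. The tension of a junction is
#' `T = |Q_a - Q_b|`, rescaled so the mean over included junctions is one;
#' `Lambda` is the corresponding eigenvalue (0 when an exactly perpendicular
#' dual exists). Disconnected dual graphs are solved and normalised per
#' component, with a warning.
#'
#' @param network a `tissue_network`; [restrict_threefold()] is applied when
#'   the `retained` flags are missing.
#' @param eigen_gap_warn relative eigen-gap below which a near-degenerate
#'   spectrum warning is issued.
#' @return object of class `inferred_tensions`: data.frame `tensions`
#'   (`junction_id`, `cell_a`, `cell_b`, `tension`, `length`, `angle`,
#'   `component`), matrix `Q` (one row per retained cell), `lambda`
#'   (per-component eigenvalues), `normalization` (per-component scale
#'   divisors), `excluded` (data.frame `junction_id`, `reason`).
#' @export
infer_tensions <- function(network, eigen_gap_warn = 1e-6,
                           max_deflations = 15) {
  if (is.null(network$junctions$retained)) network <- restrict_threefold(network)
  invisible(build_dual_topology(network))  # validates the restricted input
  jn <- network$junctions
  used <- jn$retained

  chords <- matrix(NA_real_, nrow(jn), 2)
  for (i in which(used)) {
    ep <- .junction_endpoints(network, jn[i, ])
    if (!is.null(ep)) chords[i, ] <- ep$p2 - ep$p1
  }

  # structural pruning: parts of the dual graph that admit exact spurious
  # null modes of the inner-product form, which the minimiser would latch
  # onto. A Q-node is pinned only if its incident chord directions span the
  # plane, so cells with < 2 dual edges or near-collinear chords go, as do
  # bridge edges (a lone edge between blocks leaves the perpendicular
  # relative translation unconstrained).
  prune <- function(used) {
    repeat {
      ej_idx <- which(used)
      if (!length(ej_idx)) break
      ej0 <- jn[ej_idx, , drop = FALSE]
      cellset <- unique(c(ej0$cell_a, ej0$cell_b))
      weak <- integer(0)
      for (cid in cellset) {
        inc <- ej_idx[ej0$cell_a == cid | ej0$cell_b == cid]
        if (length(inc) < 2) { weak <- c(weak, cid); next }
        u <- chords[inc, , drop = FALSE]
        u <- u / sqrt(rowSums(u^2))
        lam <- eigen(crossprod(u) / length(inc), symmetric = TRUE,
                     only.values = TRUE)$values
        if (lam[2] < 0.02) weak <- c(weak, cid)
      }
      if (length(weak)) {
        drop <- used & (jn$cell_a %in% weak | jn$cell_b %in% weak)
        if (any(drop)) {
          used[drop] <- FALSE
          jn$exclude_reason[drop] <<- "ill_constrained_cell"
          next
        }
      }
      ej0 <- jn[used, , drop = FALSE]
      if (nrow(ej0) == 0) break
      g <- igraph::graph_from_data_frame(
        data.frame(from = as.character(ej0$cell_a),
                   to = as.character(ej0$cell_b)),
        directed = FALSE)
      br <- igraph::bridges(g)
      if (!length(br)) break
      ends <- igraph::ends(g, br)
      bkey <- paste(pmin(as.integer(ends[, 1]), as.integer(ends[, 2])),
                    pmax(as.integer(ends[, 1]), as.integer(ends[, 2])))
      jkey <- paste(pmin(jn$cell_a, jn$cell_b), pmax(jn$cell_a, jn$cell_b))
      drop <- used & jkey %in% bkey
      if (!any(drop)) break
      used[drop] <- FALSE
      jn$exclude_reason[drop] <<- "bridge_junction"
    }
    used
  }

  solve_all <- function(used) {
    ej <- jn[used, , drop = FALSE]
    if (nrow(ej) == 0) stop("no junction survives dual-graph pruning")
    cells <- sort(unique(c(ej$cell_a, ej$cell_b)))
    nc <- length(cells)
    if (nc < 2) stop("need at least two retained cells sharing a junction")
    ci <- match(ej$cell_a, cells)
    cj <- match(ej$cell_b, cells)
    rmat <- chords[used, , drop = FALSE]

    comp <- .graph_components(ci, cj, nc)
    ncomp <- max(comp)
    Q <- matrix(NA_real_, nc, 2,
                dimnames = list(as.character(cells), c("x", "y")))
    lambda <- numeric(ncomp)
    gaps <- rep(Inf, ncomp)
    raw <- rep(NA_real_, nrow(ej))
    jcomp <- comp[ci]

    for (k in seq_len(ncomp)) {
      idx <- which(comp == k)
      sel <- which(jcomp == k)
      if (length(idx) < 2 || length(sel) < 1) next
      loc <- match(ci[sel], idx)
      locb <- match(cj[sel], idx)
      n <- length(idx)
      G <- matrix(0, length(sel), 2 * n)
      Hx <- matrix(0, length(sel), 2 * n)
      Hy <- matrix(0, length(sel), 2 * n)
      for (t in seq_along(sel)) {
        a <- loc[t]; b <- locb[t]; r <- rmat[sel[t], ]
        G[t, 2 * a - 1] <- r[1]; G[t, 2 * a] <- r[2]
        G[t, 2 * b - 1] <- -r[1]; G[t, 2 * b] <- -r[2]
        Hx[t, 2 * a - 1] <- 1; Hx[t, 2 * b - 1] <- -1
        Hy[t, 2 * a] <- 1; Hy[t, 2 * b] <- -1
      }
      A <- crossprod(G)
      B <- crossprod(Hx) + crossprod(Hy)
      # deflate the two translation modes: orthonormal complement basis
      t1 <- rep(c(1, 0), n) / sqrt(n)
      t2 <- rep(c(0, 1), n) / sqrt(n)
      Zb <- qr.Q(qr(cbind(t1, t2)), complete = TRUE)[, -(1:2), drop = FALSE]
      Ar <- crossprod(Zb, A %*% Zb)
      Br <- crossprod(Zb, B %*% Zb)
      R <- tryCatch(chol(Br), error = function(e)
        stop("dual component is not rigidly connected (singular constraint form)"))
      Rinv <- backsolve(R, diag(nrow(R)))
      M <- crossprod(Rinv, Ar %*% Rinv)
      M <- (M + t(M)) / 2
      es <- eigen(M, symmetric = TRUE)
      m <- ncol(M)
      lambda[k] <- es$values[m]
      if (m >= 2) {
        gaps[k] <- (es$values[m - 1] - es$values[m]) /
          max(abs(es$values[1]), 1e-300)
      }
      qv <- Zb %*% (Rinv %*% es$vectors[, m])
      Q[idx, ] <- matrix(qv, ncol = 2, byrow = TRUE)
      raw[sel] <- sqrt(rowSums((Q[idx[loc], , drop = FALSE] -
                                  Q[idx[locb], , drop = FALSE])^2))
    }
    list(ej = ej, cells = cells, comp = comp, jcomp = jcomp,
         Q = Q, lambda = lambda, gaps = gaps, raw = raw)
  }

  # deflation loop: a localised solution (most tensions vanishing, the whole
  # weight on a few junctions) signals a near-null mode crossing a narrow
  # cut of almost-parallel chords; split the Q-values at their largest gap
  # and drop the smaller block, then re-solve
  sol <- NULL
  for (pass in seq_len(max_deflations)) {
    used <- prune(used)
    sol <- solve_all(used)
    bad <- FALSE
    for (k in seq_len(max(sol$comp))) {
      sel <- which(sol$jcomp == k)
      tk <- sol$raw[sel]
      if (length(tk) < 4 || !all(is.finite(tk))) next
      if (stats::median(tk) >= 0.05 * mean(tk)) next
      bad <- TRUE
      idx <- which(sol$comp == k)
      Qk <- sol$Q[idx, , drop = FALSE]
      d <- svd(sweep(Qk, 2, colMeans(Qk)))$v[, 1]
      proj <- as.vector(Qk %*% d)
      o <- order(proj)
      gaps <- diff(proj[o])
      cutat <- which.max(gaps)
      side <- if (cutat <= length(o) / 2) o[seq_len(cutat)]
              else o[(cutat + 1):length(o)]
      block <- as.integer(rownames(sol$Q)[idx[side]])
      drop <- used & (jn$cell_a %in% block | jn$cell_b %in% block)
      if (!any(drop)) next
      used[drop] <- FALSE
      jn$exclude_reason[drop] <- "degenerate_block"
    }
    if (!bad) break
    if (pass == max_deflations) {
      warning("degenerate-mode deflation did not converge; ",
              "returning the last solution")
    }
  }

  if (any(is.finite(sol$gaps) & sol$gaps < eigen_gap_warn)) {
    warning(sprintf(
      "near-degenerate eigenvalue spectrum (relative eigen-gap %.3e)",
      min(sol$gaps)))
  }

  # normalise: mean tension one per component
  ej <- sol$ej
  tension <- sol$raw
  Q <- sol$Q
  norms <- numeric(max(sol$comp))
  for (k in seq_len(max(sol$comp))) {
    sel <- which(sol$jcomp == k)
    sc <- mean(sol$raw[sel])
    if (!is.finite(sc) || sc <= 0) {
      stop("degenerate solution: all inferred tensions are zero")
    }
    tension[sel] <- sol$raw[sel] / sc
    idx <- which(sol$comp == k)
    Q[idx, ] <- Q[idx, ] / sc
    norms[k] <- sc
  }
  if (max(sol$comp) > 1) {
    warning("dual graph has ", max(sol$comp),
            " connected components; inferring and normalising per component")
  }

  network$junctions$retained <- used
  network$junctions$exclude_reason <- jn$exclude_reason
  excl <- jn[!used, c("id", "exclude_reason")]
  names(excl) <- c("junction_id", "reason")
  structure(list(
    tensions = data.frame(junction_id = ej$id, cell_a = ej$cell_a,
                          cell_b = ej$cell_b, tension = tension,
                          length = ej$length, angle = ej$angle,
                          component = sol$jcomp),
    Q = Q, lambda = sol$lambda, normalization = norms,
    excluded = excl, schema_version = "1.0"
  ), class = "inferred_tensions")
}

#' @export
print.inferred_tensions <- function(x, ...) {
  cat("<inferred_tensions> ", nrow(x$tensions), " junctions, ",
      nrow(x$Q), " cells, ", length(x$lambda), " component(s)\n", sep = "")
  cat("  lambda:", format(x$lambda, digits = 4),
      "  mean tension:", format(mean(x$tensions$tension), digits = 6), "\n")
  invisible(x)
}

# connected components of an undirected graph given edge endpoint indices
.graph_components <- function(a, b, n) {
  adj <- vector("list", n)
  for (i in seq_along(a)) {
    adj[[a[i]]] <- c(adj[[a[i]]], b[i])
    adj[[b[i]]] <- c(adj[[b[i]]], a[i])
  }
  comp <- integer(n)
  k <- 0
  for (s in seq_len(n)) {
    if (comp[s] != 0) next
    k <- k + 1
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0]
      comp[new] <- k
      queue <- c(queue, new)
    }
  }
  comp
}

#' Force-balance residual at three-fold vertices
#'
#' At mechanical equilibrium the junctional tensions at each vertex sum to
#' zero. For every interior three-fold vertex whose incident junctions all
#' carry a tension, the residual is `| sum_j T_j u_jv |` where `u_jv` is the
#' unit end-to-end chord vector pointing away from the vertex. Vertices
#' touching a junction without a tension are skipped and counted.
#'
#' @param network a `tissue_network`.
#' @param tensions an `inferred_tensions` object or a data.frame with
#'   `junction_id` and `tension` columns.
#' @return list of class `force_residuals`: data.frame `residuals`
#'   (`vertex_id`, `residual`), `median`, `n_skipped`.
#' @export
force_balance_residual <- function(network, tensions) {
  tdf <- if (inherits(tensions, "inferred_tensions")) tensions$tensions else tensions
  tmap <- stats::setNames(tdf$tension, as.character(tdf$junction_id))

  jn <- network$junctions
  vv <- network$vertices
  res <- numeric(0); vid <- integer(0); deg <- integer(0); skipped <- 0L
  for (i in seq_len(nrow(vv))) {
    if (vv$degree[i] < 2) next
    v <- vv$id[i]
    inc <- jn[(!is.na(jn$v1) & jn$v1 == v) | (!is.na(jn$v2) & jn$v2 == v), ,
              drop = FALSE]
    tt <- tmap[as.character(inc$id)]
    if (any(is.na(tt))) { skipped <- skipped + 1L; next }
    fx <- fy <- 0
    bad <- FALSE
    for (r in seq_len(nrow(inc))) {
      ep <- .junction_endpoints(network, inc[r, ])
      if (is.null(ep)) { bad <- TRUE; break }
      u <- if (inc$v1[r] == v) ep$p2 - ep$p1 else ep$p1 - ep$p2
      u <- u / sqrt(sum(u^2))
      fx <- fx + tt[r] * u[1]; fy <- fy + tt[r] * u[2]
    }
    if (bad) { skipped <- skipped + 1L; next }
    vid <- c(vid, v); res <- c(res, sqrt(fx^2 + fy^2)); deg <- c(deg, vv$degree[i])
  }
  three <- res[deg == 3]
  structure(list(residuals = data.frame(vertex_id = vid, residual = res,
                                        degree = deg),
                 median = if (length(three)) stats::median(three) else
                   if (length(res)) stats::median(res) else NA_real_,
                 n_skipped = skipped),
            class = "force_residuals")
}
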