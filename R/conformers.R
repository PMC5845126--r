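# Conformer generation by penalty-function distance embedding.
#
# Heavy atoms only.  The geometry model is a set of distance restraints:
# bond lengths from covalent radii (order-scaled), 1-3 distances from ideal
# angles by hybridization (sp3 109.47, sp2/aromatic 120, sp 180), all-pair
# distances inside aromatic rings from a regular-polygon template (making
# rings planar and rigid), and a one-sided repulsion floor for non-bonded
# pairs.  Starting coordinates come from a seeded BFS chain walk (inherited
# atoms start near their inherited coordinates); BFGS minimizes the penalty.
# Different seeds give different torsional minima, which is the conformer
# ensemble.  This is a deliberately simple, deterministic stand-in for a
# force-field conformer generator; see the methods vignette for what it does
# and does not capture.

conformer_restraints <- function(mol) {
  n <- n_atoms(mol)
  adj <- adjacency(mol)
  el <- mol$atoms$element
  # hybridization-dependent angle at the central atom
  hyb <- rep.int(3L, n)
  if (nrow(mol$bonds)) {
    for (i in seq_len(nrow(mol$bonds))) {
      bd <- mol$bonds[i, ]
      if (bd$order == 3L) { hyb[bd$a] <- 1L; hyb[bd$b] <- 1L }
      else if (bd$order == 2L || bd$arom) {
        hyb[bd$a] <- min(hyb[bd$a], 2L); hyb[bd$b] <- min(hyb[bd$b], 2L)
      }
    }
    # cumulated double bonds (allenes, isocyanates): central atom is linear
    ndbl <- integer(n)
    for (i in which(mol$bonds$order == 2L)) {
      ndbl[mol$bonds$a[i]] <- ndbl[mol$bonds$a[i]] + 1L
      ndbl[mol$bonds$b[i]] <- ndbl[mol$bonds$b[i]] + 1L
    }
    hyb[ndbl >= 2L] <- 1L
  }
  pairs <- list()
  addp <- function(i, j, d0, w, lower_only = FALSE) {
    pairs[[length(pairs) + 1L]] <<- c(min(i, j), max(i, j), d0, w, lower_only)
  }
  for (i in seq_len(nrow(mol$bonds))) {
    bd <- mol$bonds[i, ]
    addp(bd$a, bd$b,
         ideal_bond_length(el[bd$a], el[bd$b], bd$order, bd$arom), 8, FALSE)
  }
  bidx <- bond_index(mol)
  blen <- function(i, j) {
    bi <- bidx[[paste(min(i, j), max(i, j))]]
    ideal_bond_length(el[i], el[j], mol$bonds$order[bi], mol$bonds$arom[bi])
  }
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) < 2L) next
    theta <- switch(hyb[j], `1` = pi, `2` = 2 * pi / 3, 109.47 * pi / 180)
    if (is.null(theta)) theta <- 109.47 * pi / 180
    for (x in seq_along(nb)) for (y in seq_len(x - 1L)) {
      i <- nb[x]; k <- nb[y]
      dij <- blen(i, j); djk <- blen(j, k)
      addp(i, k, sqrt(dij^2 + djk^2 - 2 * dij * djk * cos(theta)), 3, FALSE)
    }
  }
  rings <- find_rings(mol)
  for (r in rings) {
    if (!all(mol$atoms$arom[r])) next
    m <- length(r); s <- 1.39
    for (x in seq_len(m)) for (y in seq_len(x - 1L)) {
      sep <- min(abs(x - y), m - abs(x - y))
      if (sep < 2L) next
      addp(r[x], r[y], s * sin(sep * pi / m) / sin(pi / m), 3, FALSE)
    }
  }
  constrained <- paste(vapply(pairs, `[`, 0, 1L), vapply(pairs, `[`, 0, 2L))
  gd <- lapply(seq_len(n), function(v) graph_dist(adj, v, n))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (paste(i, j) %in% constrained) next
    d <- gd[[i]][j]
    if (is.na(d) || d >= 3L) addp(i, j, 0.78 * (vdw_radius(el[i]) + vdw_radius(el[j])),
                                  1, TRUE)
  }
  mat <- do.call(rbind, pairs)
  colnames(mat) <- c("i", "j", "d0", "w", "lower")
  mat
}

embed_objective <- function(x, restr, n) {
  X <- matrix(x, n, 3L)
  D <- X[restr[, "i"], , drop = FALSE] - X[restr[, "j"], , drop = FALSE]
  d <- sqrt(rowSums(D^2)) + 1e-12
  dev <- d - restr[, "d0"]
  act <- restr[, "lower"] == 0 | dev < 0
  sum(restr[act, "w"] * dev[act]^2)
}

embed_gradient <- function(x, restr, n) {
  X <- matrix(x, n, 3L)
  D <- X[restr[, "i"], , drop = FALSE] - X[restr[, "j"], , drop = FALSE]
  d <- sqrt(rowSums(D^2)) + 1e-12
  dev <- d - restr[, "d0"]
  act <- restr[, "lower"] == 0 | dev < 0
  coef <- ifelse(act, 2 * restr[, "w"] * dev / d, 0)
  G <- matrix(0, n, 3L)
  for (c3 in 1:3) {
    gc <- coef * D[, c3]
    G[, c3] <- G[, c3] +
      tapply_sum(restr[, "i"], gc, n) - tapply_sum(restr[, "j"], gc, n)
  }
  as.numeric(G)
}

tapply_sum <- function(idx, val, n) {
  out <- numeric(n)
  s <- rowsum(val, idx)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

embed_init <- function(mol, inherited = NULL) {
  n <- n_atoms(mol)
  adj <- adjacency(mol)
  X <- matrix(NA_real_, n, 3L)
  has_inh <- !is.null(inherited) && any(stats::complete.cases(inherited))
  if (has_inh) {
    ok <- stats::complete.cases(inherited)
    X[ok, ] <- inherited[ok, , drop = FALSE] +
      matrix(stats::rnorm(3 * sum(ok), 0, 0.05), sum(ok), 3L)
  }
  placed <- which(stats::complete.cases(X))
  todo <- setdiff(seq_len(n), placed)
  if (!length(placed) && length(todo)) {
    X[todo[1L], ] <- 0
    placed <- todo[1L]; todo <- todo[-1L]
  }
  while (length(todo)) {
    nxt <- NULL
    for (v in todo) if (any(adj[[v]] %in% placed)) { nxt <- v; break }
    if (is.null(nxt)) {  # disconnected piece: drop it at a random offset
      nxt <- todo[1L]
      X[nxt, ] <- stats::rnorm(3, 0, 4)
    } else {
      parent <- intersect(adj[[nxt]], placed)[1L]
      gp <- intersect(adj[[parent]], placed)
      dir <- stats::rnorm(3)
      if (length(gp)) dir <- dir + 1.2 * (X[parent, ] - X[gp[1L], ]) /
          max(sqrt(sum((X[parent, ] - X[gp[1L], ])^2)), 1e-6)
      dir <- dir / sqrt(sum(dir^2))
      X[nxt, ] <- X[parent, ] + dir * 1.5
    }
    placed <- c(placed, nxt); todo <- setdiff(todo, nxt)
  }
  X
}

#' Generate a conformer ensemble
#'
#' @param product a `product_record`, or a `mol_graph`
#' @param k maximum ensemble size (default 30, the pipeline's standard
#'   ensemble size)
#' @param seed integer seed; the ensemble is a pure function of
#'   (molecule, k, seed)
#' @return list of conformers, each list(mol, coords, strain); distinct up to
#'   a rounded distance-matrix signature, sorted by ascending strain
#' @export
generate_conformers <- function(product, k = 30L, seed = 2024L) {
  stopifnot(k >= 1L)
  mol <- if (inherits(product, "product_record")) product$product else product
  inherited <- if (inherits(product, "product_record")) product$inherited_coords else NULL
  n <- n_atoms(mol)
  if (n == 0L) stop_format("cannot embed an empty molecule")
  restr <- conformer_restraints(mol)
  out <- list(); seen <- character(0)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  for (attempt in seq_len(k)) {
    set.seed(seed + 7919L * (attempt - 1L))
    X0 <- embed_init(mol, if (attempt == 1L) inherited else
      if (!is.null(inherited) && attempt %% 2L == 0L) inherited else NULL)
    res <- tryCatch(
      stats::optim(as.numeric(X0), embed_objective, embed_gradient,
                   restr = restr, n = n, method = "BFGS",
                   control = list(maxit = 300L, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(res))
      stop_format("conformer embedding failed for molecule '",
                  write_smiles(mol), "'")
    X <- matrix(res$par, n, 3L)
    sig <- conformer_signature(X)
    if (sig %in% seen) next
    seen <- c(seen, sig)
    out[[length(out) + 1L]] <- list(mol = mol, coords = X, strain = res$value)
  }
  out[order(vapply(out, `[[`, 0, "strain"))]
}

conformer_signature <- function(X) {
  d <- stats::dist(X)
  paste(round(sort(as.numeric(d)) / 0.35), collapse = ",")
}
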