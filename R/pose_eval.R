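# Pose evaluation: volume-overlap alignment onto the preserved space, the
# growth-direction check, the deterministic pairwise interaction scorer, and
# group efficiency.

# ---- rigid alignment -------------------------------------------------------

#' Kabsch superposition: rotation/translation taking P onto Q (least squares)
#' @noRd
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2L, cp)) %*% sweep(Q, 2L, cq)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = cq - as.numeric(R %*% cp))
}

apply_rigid <- function(X, R, t) sweep(X %*% t(R), 2L, -t)

# Gaussian-sphere volume overlap (ROCS-style): atoms are spherical Gaussians
# rho(r) = p * exp(-alpha r^2) with p = 2.7 and alpha = 2.418 / r_vdw^2; the
# shared volume is the pairwise overlap integral.
.GAUSS_P <- 2.7
.GAUSS_KAPPA <- 2.418

gaussian_overlap <- function(A, B, ra, rb) {
  aa <- .GAUSS_KAPPA / ra^2
  ab <- .GAUSS_KAPPA / rb^2
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  S <- outer(aa, ab, "+")
  Pr <- outer(aa, ab, "*") / S
  sum(.GAUSS_P^2 * (pi / S)^1.5 * exp(-Pr * pmax(d2, 0)))
}

#' Align a conformer onto the preserved space of the query
#'
#' Finds the preserved fragment in the conformer's molecule, rigidly
#' superposes it on the fragment's reference pose (Kabsch start, then a short
#' Nelder-Mead polish of the 6 rigid parameters maximizing Gaussian volume
#' overlap) and applies the transform to the whole conformer.  Internal
#' geometry is untouched.  With several symmetry-equivalent embeddings the
#' best-overlap one wins.
#'
#' @param conf list(mol, coords) conformer
#' @param frag a `preserved_fragment`
#' @return list(mol, coords (aligned), overlap (fraction of the fragment's
#'   self-overlap volume, in `[0,1]`), match)
#' @export
align_to_preserved <- function(conf, frag) {
  matches <- match_substructure(frag$pattern, conf$mol, max_matches = 24L)
  if (!length(matches))
    stop_format("preserved fragment not found in conformer's molecule")
  ref <- frag$reference_coords
  r_ref <- vdw_radius(frag$pattern$atoms$element)
  v_ref <- gaussian_overlap(ref, ref, r_ref, r_ref)
  best <- NULL
  for (m in matches) {
    P <- conf$coords[m, , drop = FALSE]
    r_p <- vdw_radius(conf$mol$atoms$element[m])
    tr <- kabsch(P, ref)
    par0 <- c(0, 0, 0, 0, 0, 0)  # perturbation around the Kabsch transform
    base <- apply_rigid(conf$coords, tr$R, tr$t)
    ctr <- colMeans(base[m, , drop = FALSE])
    objective <- function(par) {
      Xm <- rigid_perturb(base[m, , drop = FALSE], par, ctr)
      -gaussian_overlap(Xm, ref, r_p, r_ref)
    }
    opt <- stats::optim(par0, objective, method = "Nelder-Mead",
                        control = list(maxit = 120L))
    ov <- min(-opt$value / v_ref, 1)
    if (is.null(best) || ov > best$overlap) {
      best <- list(mol = conf$mol,
                   coords = rigid_perturb(base, opt$par, ctr),
                   overlap = max(ov, 0), match = m)
    }
  }
  best
}

rigid_perturb <- function(X, par, ctr) {
  ang <- par[4:6]
  Rx <- rot3(ang[1L], 1L); Ry <- rot3(ang[2L], 2L); Rz <- rot3(ang[3L], 3L)
  R <- Rz %*% Ry %*% Rx
  sweep(sweep(X, 2L, ctr) %*% t(R), 2L, -(ctr + par[1:3]))
}

rot3 <- function(theta, axis) {
  c_ <- cos(theta); s_ <- sin(theta)
  m <- diag(3)
  ix <- setdiff(1:3, axis)
  m[ix[1L], ix[1L]] <- c_; m[ix[2L], ix[2L]] <- c_
  m[ix[1L], ix[2L]] <- -s_; m[ix[2L], ix[1L]] <- s_
  m
}

# ---- interaction targets and the direction check ---------------------------

#' A receptor interaction site the grown ligand should reach
#'
#' @param id label
#' @param anchor length-3 numeric, Angstrom
#' @param kind one of `"hbond-donor"`, `"hbond-acceptor"`, `"hydrophobic"`,
#'   `"aromatic"` — the chemotype the *ligand* must present at the site
#' @param satisfied_radius Angstrom; the target counts as satisfied when a
#'   compatible new atom lies within this radius of the anchor
#' @return an `interaction_target`
#' @export
interaction_target <- function(id, anchor, kind, satisfied_radius = 4) {
  kind <- match.arg(kind, c("hbond-donor", "hbond-acceptor", "hydrophobic",
                            "aromatic"))
  stopifnot(length(anchor) == 3L, all(is.finite(anchor)), satisfied_radius > 0)
  structure(list(id = id, anchor = as.numeric(anchor), kind = kind,
                 satisfied_radius = satisfied_radius),
            class = "interaction_target")
}

atom_compatible <- function(mol, idx, kind) {
  el <- mol$atoms$element[idx]
  switch(kind,
         "hbond-donor" = el %in% c("N", "O") & mol$atoms$hcount[idx] > 0L,
         "hbond-acceptor" = el %in% c("N", "O"),
         "hydrophobic" = el == "C",
         "aromatic" = mol$atoms$arom[idx])
}

#' Direction check for a growth step
#'
#' TRUE iff the newly added atoms moved strictly closer to the target anchor
#' than anything in the previous state, and the nearest new atom is
#' chemotype-compatible with the target.
#'
#' @param aligned list(mol, coords) aligned conformer
#' @param new_atoms indices of atoms introduced by the step (nonempty)
#' @param target an `interaction_target`
#' @param previous_best_distance Angstrom
#' @return logical
#' @export
check_direction <- function(aligned, new_atoms, target,
                            previous_best_distance) {
  stopifnot(length(new_atoms) > 0L)
  d <- sqrt(colSums((t(aligned$coords[new_atoms, , drop = FALSE]) -
                       target$anchor)^2))
  i <- which.min(d)
  d[i] < previous_best_distance &&
    atom_compatible(aligned$mol, new_atoms[i], target$kind)
}

# ---- the scorer ------------------------------------------------------------

#' Default scorer weights
#' @export
default_score_weights <- function() list(w_hb = 1.0, w_ph = 0.2, w_cl = 1.0,
                                         clash_penalty = 5.0)

hb_well <- function(d) {
  ifelse(d < 2.2, 0,
  ifelse(d < 2.6, -(d - 2.2) / 0.4,
  ifelse(d <= 3.2, -1,
  ifelse(d < 4.0, -(4.0 - d) / 0.8, 0))))
}

ph_well <- function(d) {
  ifelse(d <= 4.5, -1, ifelse(d < 5.5, -(5.5 - d), 0))
}

ligand_hb_types <- function(mol) {
  el <- mol$atoms$element
  list(donor = which(el %in% c("N", "O") & mol$atoms$hcount > 0L),
       acceptor = which(el %in% c("N", "O")),
       carbon = which(el == "C"))
}

#' Score a ligand pose against the receptor
#'
#' Deterministic pairwise scorer (more negative is better):
#' hydrogen bonds over ligand-donor/receptor-acceptor and
#' ligand-acceptor/receptor-donor pairs with a piecewise-linear well (-1 on
#' 2.6-3.2 A, 0 at 2.2 and 4.0 A); hydrophobic carbon/carbon contacts (-1 up
#' to 4.5 A, 0 beyond 5.5 A); +5 clash per heavy-atom pair closer than 0.8x
#' the vdW-radius sum.  Weights w_hb = 1.0, w_ph = 0.2, w_cl = 1.0.
#'
#' @param aligned list(mol, coords)
#' @param rec a `receptor`
#' @param weights see [default_score_weights()]
#' @return energy (scorer units)
#' @export
score_pose <- function(aligned, rec, weights = default_score_weights()) {
  X <- aligned$coords
  if (is.null(X) || any(!is.finite(X)))
    stop_format("scoring error: pose has missing coordinates")
  R <- receptor_coords(rec)
  ty <- ligand_hb_types(aligned$mol)
  E <- 0
  pairs_d <- function(li, ri) {
    if (!length(li) || !length(ri)) return(numeric(0))
    A <- X[li, , drop = FALSE]; B <- R[ri, , drop = FALSE]
    sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B), 0))
  }
  E <- E + weights$w_hb * (sum(hb_well(pairs_d(ty$donor, rec$acceptors))) +
                             sum(hb_well(pairs_d(ty$acceptor, rec$donors))))
  E <- E + weights$w_ph * sum(ph_well(pairs_d(ty$carbon, rec$hydrophobic)))
  dall <- pairs_d(seq_len(nrow(X)), seq_len(nrow(R)))
  lim <- outer(vdw_radius(aligned$mol$atoms$element),
               vdw_radius(rec$atoms$element), "+") * 0.8
  E + weights$w_cl * weights$clash_penalty * sum(dall < lim)
}

#' Group efficiency of a growth step
#'
#' Incremental binding energy per added heavy atom,
#' GE = (E_new - E_prev) / (n_new - n_prev); downstream acceptance requires
#' GE strictly below the threshold (-0.1 by default).
#'
#' @param E_new,E_prev energies (scorer units)
#' @param n_new,n_prev heavy-atom counts (n_new > n_prev)
#' @return GE
#' @export
group_efficiency <- function(E_new, E_prev, n_new, n_prev) {
  if (n_new <= n_prev)
    stop_format("degenerate growth: n_new (", n_new, ") must exceed n_prev (",
                n_prev, ")")
  (E_new - E_prev) / (n_new - n_prev)
}
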