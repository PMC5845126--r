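# The growth engine: seed -> rule-based products -> pose evaluation ->
# best-group-efficiency conformer becomes the next reactant, per interaction
# target, followed by property filtering, refinement-based ranking and
# synthetic-route export.

#' Growth configuration
#'
#' @param n_conformers conformer ensemble size per product (default 30)
#' @param ge_threshold group-efficiency acceptance threshold; a step is
#'   accepted only if GE is strictly below it (default -0.1)
#' @param mw_max,clogp_max property-filter bounds, strict `<` (600, 5)
#' @param beam beam width over growth states (default 3; 1 = greedy)
#' @param step_cap max accepted reaction steps per interaction target (2)
#' @param seed master seed for every stochastic call
#' @param refine_sweeps coordinate-descent sweeps in pose refinement (2)
#' @param weights scorer weights, see [default_score_weights()]
#' @export
grow_config <- function(n_conformers = 30L, ge_threshold = -0.1,
                        mw_max = 600, clogp_max = 5, beam = 3L,
                        step_cap = 2L, seed = 2024L, refine_sweeps = 2L,
                        weights = default_score_weights()) {
  stopifnot(n_conformers >= 1L, beam >= 1L, step_cap >= 0L, mw_max > 0,
            refine_sweeps >= 0L)
  list(n_conformers = as.integer(n_conformers), ge_threshold = ge_threshold,
       mw_max = mw_max, clogp_max = clogp_max, beam = as.integer(beam),
       step_cap = as.integer(step_cap), seed = as.integer(seed),
       refine_sweeps = as.integer(refine_sweeps), weights = weights)
}

# deterministic 31-bit seed derived from the master seed and a string
derive_seed <- function(seed, key) {
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 131 + cc) %% 1862270839
  as.integer((seed %% 104729) * 20011 + h) %% 2147483647L
}

target_distances <- function(coords, targets) {
  vapply(targets, function(tg)
    min(sqrt(colSums((t(coords) - tg$anchor)^2))), 0)
}

target_satisfied <- function(mol, coords, new_atoms, tg) {
  comp <- new_atoms[atom_compatible(mol, new_atoms, tg$kind)]
  if (!length(comp)) return(FALSE)
  d <- sqrt(colSums((t(coords[comp, , drop = FALSE]) - tg$anchor)^2))
  any(d <= tg$satisfied_radius)
}

#' Grow seeds toward interaction targets
#'
#' For each seed, targets are addressed strictly in order.  At every step the
#' engine enumerates rule-based products of the current molecule, evaluates
#' up to `n_conformers` conformers per product aligned to the preserved
#' space, keeps per product the best-GE conformer passing the direction
#' check, accepts the step only if GE is strictly below `ge_threshold`, and
#' beam-keeps the top-`beam` states.  A target is satisfied when a
#' compatible new atom lies within its `satisfied_radius`; each target gets
#' at most `step_cap` accepted steps.  Every emitted candidate carries its
#' full synthetic route.
#'
#' @param seeds list of `building_block` (typically from [find_seed_blocks()])
#' @param targets ordered list of `interaction_target`
#' @param db a `rule_db` with block index
#' @param library list of `building_block`
#' @param rec a `receptor`
#' @param frag a `preserved_fragment`
#' @param config see [grow_config()]
#' @param cache optional conformer cache environment (reusable across calls
#'   that share the same `n_conformers` and master seed)
#' @return list of candidate states (class `growth_candidate`), unfiltered;
#'   pass through [filter_candidates()] and [rank_candidates()]
#' @export
grow <- function(seeds, targets, db, library, rec, frag,
                 config = grow_config(),
                 cache = new.env(parent = emptyenv())) {
  if (!length(seeds)) stop_format("no seeds supplied")
  out <- list()
  for (seed_block in seeds) {
    st <- seed_state(seed_block, targets, rec, frag, config, cache)
    if (is.null(st)) next
    beam <- list(st)
    for (tg in targets) {
      finished <- Filter(function(s)
        isTRUE(s$satisfied[[tg$id]]), beam)
      active <- Filter(function(s) !isTRUE(s$satisfied[[tg$id]]), beam)
      step <- 0L
      while (length(active) && step < config$step_cap) {
        step <- step + 1L
        expansions <- list()
        for (s in active) {
          exp_s <- expand_state(s, tg, db, library, rec, frag, config, cache,
                                targets)
          if (!length(exp_s)) finished <- c(finished, list(s))
          else expansions <- c(expansions, exp_s)
        }
        if (!length(expansions)) { active <- list(); break }
        ge <- vapply(expansions, `[[`, 0, "step_ge")
        en <- vapply(expansions, `[[`, 0, "energy")
        keep <- order(ge, en)[seq_len(min(config$beam, length(expansions)))]
        nxt <- expansions[keep]
        finished <- c(finished, Filter(function(s)
          isTRUE(s$satisfied[[tg$id]]), nxt))
        active <- Filter(function(s) !isTRUE(s$satisfied[[tg$id]]), nxt)
      }
      pool <- c(finished, active)
      pool <- dedup_states(pool)
      en <- vapply(pool, `[[`, 0, "energy")
      beam <- pool[order(en)[seq_len(min(config$beam, length(pool)))]]
    }
    out <- c(out, beam)
  }
  out <- dedup_states(out)
  if (!length(out))
    warning("no seed matched any rule; empty candidate list")
  lapply(out, function(s) { class(s) <- "growth_candidate"; s })
}

seed_state <- function(seed_block, targets, rec, frag, config, cache) {
  confs <- cached_conformers(seed_block$mol, NULL, config, cache,
                             key = canonical_key(seed_block$mol))
  best <- NULL
  for (cf in confs) {
    al <- tryCatch(align_to_preserved(cf, frag),
                   rxngrow_format_error = function(e) NULL)
    if (is.null(al)) next
    E <- score_pose(al, rec, config$weights)
    if (is.null(best) || E < best$energy)
      best <- list(mol = seed_block$mol, coords = al$coords, energy = E,
                   route = list(), seed_id = seed_block$id,
                   key = canonical_key(seed_block$mol))
  }
  if (is.null(best)) return(NULL)
  best$best_dist <- stats::setNames(target_distances(best$coords, targets),
                                    vapply(targets, `[[`, "", "id"))
  # a target can already be satisfied by the bare seed only through new
  # atoms, of which there are none yet
  best$satisfied <- stats::setNames(as.list(rep(FALSE, length(targets))),
                                    names(best$best_dist))
  best$step_ge <- 0
  best
}

expand_state <- function(s, tg, db, library, rec, frag, config, cache,
                         targets) {
  prods <- enumerate_products(s$mol, db, library, coords = s$coords,
                              reactant_id = s$key)
  n_prev <- n_atoms(s$mol)
  out <- list()
  for (pr in prods) {
    if (!has_substructure(frag$pattern, pr$product)) next
    # conformers are a pure function of (molecule, k, seed): inherited
    # coordinates are deliberately NOT used here so that the ensemble of a
    # molecule is identical no matter which route reached it (the preserved-
    # space alignment re-poses the core anyway); generate_conformers() still
    # honors inheritance when handed a product_record directly
    confs <- cached_conformers(pr$product, NULL, config, cache, key = pr$key)
    best <- NULL
    for (cf in confs) {
      al <- tryCatch(align_to_preserved(cf, frag),
                     rxngrow_format_error = function(e) NULL)
      if (is.null(al)) next
      if (!check_direction(al, pr$new_atoms, tg, s$best_dist[[tg$id]])) next
      E <- score_pose(al, rec, config$weights)
      ge <- group_efficiency(E, s$energy, n_atoms(pr$product), n_prev)
      if (is.null(best) || ge < best$step_ge)
        best <- list(coords = al$coords, energy = E, step_ge = ge)
    }
    if (is.null(best) || !ge_acceptable(best$step_ge, config)) next
    ns <- list(mol = pr$product, coords = best$coords, energy = best$energy,
               route = c(s$route, list(list(
                 rule = pr$rule_id, participant = pr$participant_id,
                 reactant_key = s$key, product_key = pr$key,
                 energy = best$energy, ge = best$step_ge))),
               seed_id = s$seed_id, key = pr$key, step_ge = best$step_ge)
    ns$best_dist <- pmin(s$best_dist, target_distances(ns$coords, targets))
    ns$satisfied <- s$satisfied
    ns$satisfied[[tg$id]] <- target_satisfied(ns$mol, ns$coords, pr$new_atoms,
                                              tg)
    out[[length(out) + 1L]] <- ns
  }
  out
}

cached_conformers <- function(mol, inherited, config, cache, key) {
  ck <- paste0(key, "#", config$n_conformers)
  hit <- get0(ck, envir = cache)
  if (!is.null(hit)) return(hit)
  obj <- if (is.null(inherited)) mol else
    structure(list(product = mol, inherited_coords = inherited),
              class = "product_record")
  confs <- generate_conformers(obj, k = config$n_conformers,
                               seed = derive_seed(config$seed, key))
  assign(ck, confs, envir = cache)
  confs
}

dedup_states <- function(states) {
  if (!length(states)) return(states)
  keys <- vapply(states, `[[`, "", "key")
  en <- vapply(states, `[[`, 0, "energy")
  keep <- !logical(length(states))
  for (k in unique(keys)) {
    idx <- which(keys == k)
    if (length(idx) > 1L) keep[idx[-which.min(en[idx])[1L]]] <- FALSE
  }
  states[keep]
}

#' @export
print.growth_candidate <- function(x, ...) {
  cat(sprintf("<growth_candidate %s: E = %.3f, %d step(s), seed %s>\n",
              write_smiles(x$mol, keep_maps = FALSE), x$energy,
              length(x$route), x$seed_id))
  invisible(x)
}

#' Acceptance predicates
#'
#' A growth step is accepted iff its group efficiency is strictly below
#' `ge_threshold`; a candidate passes the property filter iff MW is strictly
#' below `mw_max` and cLogP strictly below `clogp_max`.
#'
#' @param ge group efficiency of a step
#' @param config see [grow_config()]
#' @export
ge_acceptable <- function(ge, config = grow_config()) {
  is.finite(ge) && ge < config$ge_threshold
}

#' @rdname ge_acceptable
#' @param descriptors output of [compute_descriptors()]
#' @export
passes_filters <- function(descriptors, config = grow_config()) {
  descriptors$molecular_weight < config$mw_max &&
    descriptors$clogp < config$clogp_max
}

#' Property filter: MW < mw_max and cLogP < clogp_max (strict)
#'
#' @param cands list of `growth_candidate`
#' @param config see [grow_config()]
#' @return the candidates that pass, each with `$descriptors` attached
#' @export
filter_candidates <- function(cands, config = grow_config()) {
  out <- list()
  for (cd in cands) {
    cd$descriptors <- compute_descriptors(cd$mol)
    if (passes_filters(cd$descriptors, config))
      out[[length(out) + 1L]] <- cd
  }
  out
}

#' Refine and rank candidates by receptor binding energy
#'
#' Each pose is locally refined by rigid-body + torsion coordinate descent on
#' the built-in scorer (fixed budget, deterministic, never increases the
#' energy), then candidates are sorted by ascending refined energy; ties
#' break by fewer heavy atoms, then seed/key.
#'
#' @param cands list of `growth_candidate` (filtered)
#' @param rec a `receptor`
#' @param config see [grow_config()]
#' @return ordered candidates with `$energy` refined and `$rank` assigned
#' @export
rank_candidates <- function(cands, rec, config = grow_config()) {
  cands <- lapply(cands, function(cd) {
    ref <- refine_pose(cd$mol, cd$coords, rec, config)
    cd$coords <- ref$coords; cd$energy <- ref$energy
    cd
  })
  en <- vapply(cands, `[[`, 0, "energy")
  ha <- vapply(cands, function(cd) n_atoms(cd$mol), 0L)
  ky <- vapply(cands, `[[`, "", "key")
  ord <- order(en, ha, ky, method = "radix")
  cands <- cands[ord]
  for (i in seq_along(cands)) cands[[i]]$rank <- i
  cands
}

#' Local pose refinement (rigid + torsion coordinate descent)
#'
#' @param mol a `mol_graph`
#' @param coords pose
#' @param rec receptor
#' @param config see [grow_config()]
#' @return list(coords, energy) with energy <= the input pose's energy
#' @export
refine_pose <- function(mol, coords, rec, config = grow_config()) {
  E <- score_pose(list(mol = mol, coords = coords), rec, config$weights)
  rot_bonds <- rotatable_bonds(mol)
  ctr <- colMeans(coords)
  for (sweep_i in seq_len(config$refine_sweeps)) {
    # rigid translations and rotations
    for (ax in 1:3) for (sgn in c(-1, 1)) {
      cand <- coords; cand[, ax] <- cand[, ax] + sgn * 0.15
      Ec <- score_pose(list(mol = mol, coords = cand), rec, config$weights)
      if (Ec < E) { coords <- cand; E <- Ec }
      R <- rot3(sgn * 3 * pi / 180, ax)
      cand <- sweep(sweep(coords, 2L, ctr) %*% t(R), 2L, -ctr)
      Ec <- score_pose(list(mol = mol, coords = cand), rec, config$weights)
      if (Ec < E) { coords <- cand; E <- Ec }
    }
    # torsions
    for (rb in rot_bonds) for (ang in c(-8, 8) * pi / 180) {
      cand <- rotate_torsion(coords, rb$axis_a, rb$axis_b, rb$moving, ang)
      Ec <- score_pose(list(mol = mol, coords = cand), rec, config$weights)
      if (Ec < E) { coords <- cand; E <- Ec }
    }
  }
  list(coords = coords, energy = E)
}

rotatable_bonds <- function(mol) {
  if (!nrow(mol$bonds)) return(list())
  rings <- find_rings(mol)
  in_ring <- rep.int(FALSE, nrow(mol$bonds))
  bidx <- bond_index(mol)
  for (r in rings) {
    rc <- c(r, r[1L])
    for (k in seq_along(r))
      in_ring[bidx[[paste(min(rc[k], rc[k + 1L]), max(rc[k], rc[k + 1L]))]]] <- TRUE
  }
  deg <- degrees(mol)
  adj <- adjacency(mol)
  out <- list()
  for (i in seq_len(nrow(mol$bonds))) {
    if (in_ring[i] || mol$bonds$order[i] != 1L || mol$bonds$arom[i]) next
    a <- mol$bonds$a[i]; b <- mol$bonds$b[i]
    if (deg[a] < 2L || deg[b] < 2L) next
    moving <- side_atoms(adj, b, a, n_atoms(mol))
    if (length(moving) > n_atoms(mol) / 2) {
      moving <- side_atoms(adj, a, b, n_atoms(mol))
      out[[length(out) + 1L]] <- list(axis_a = b, axis_b = a, moving = moving)
    } else out[[length(out) + 1L]] <- list(axis_a = a, axis_b = b,
                                           moving = moving)
  }
  out
}

# atoms on `from`'s side when the from-excl bond is cut (excl side excluded)
side_atoms <- function(adj, from, excl, n) {
  seen <- logical(n); seen[excl] <- TRUE; seen[from] <- TRUE
  queue <- from
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  out <- which(seen); setdiff(out, excl)
}

rotate_torsion <- function(coords, a, b, moving, ang) {
  axis <- coords[b, ] - coords[a, ]
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  coords[moving, ] <- sweep(sweep(coords[moving, , drop = FALSE], 2L,
                                  coords[a, ]) %*% t(R), 2L,
                            -coords[a, ])
  coords
}

#' Export a candidate's synthetic route
#'
#' @param cand a `growth_candidate`
#' @return a `route_document`: list(seed, final_key, final_smiles, steps);
#'   serialize with [write_routes_json()]
#' @export
export_route <- function(cand) {
  structure(list(
    seed = cand$seed_id,
    final_key = cand$key,
    final_smiles = write_smiles(cand$mol, keep_maps = FALSE),
    energy = cand$energy,
    steps = lapply(cand$route, function(st) list(
      rule = st$rule, participant = st$participant,
      reactant_key = st$reactant_key, product_key = st$product_key))),
    class = "route_document")
}

#' Replay a route through the virtual-synthesis machinery
#'
#' Starting from the seed block, applies each recorded (rule, participant)
#' step and checks that the recorded product key is reproduced; returns the
#' final molecule.  A mismatch is an internal consistency error.
#'
#' @param route a `route_document`
#' @param db rule database
#' @param library block library
#' @return the rebuilt `mol_graph`
#' @export
replay_route <- function(route, db, library) {
  blocks <- stats::setNames(library, vapply(library, `[[`, "", "id"))
  cur <- blocks[[route$seed]]$mol
  for (st in route$steps) {
    prods <- enumerate_products(cur, db, library)
    hit <- Filter(function(p) p$rule_id == st$rule &&
                    identical(p$participant_id, st$participant) &&
                    p$key == st$product_key, prods)
    if (!length(hit))
      stop("route replay mismatch at rule '", st$rule,
           "': recorded product not regenerated")
    cur <- hit[[1L]]$product
  }
  if (canonical_key(cur) != route$final_key)
    stop("route replay mismatch: final molecule differs from candidate")
  cur
}

#' Write / read route documents as JSON
#' @param routes list of `route_document`
#' @param path output path
#' @export
write_routes_json <- function(routes, path) {
  jsonlite::write_json(lapply(routes, unclass), path, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  invisible(path)
}

#' @rdname write_routes_json
#' @export
read_routes_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(obj, function(r) structure(r, class = "route_document"))
}

#' Human-readable route text
#' @param route a `route_document`
#' @export
format_route <- function(route) {
  lines <- sprintf("seed: %s", route$seed)
  for (i in seq_along(route$steps)) {
    st <- route$steps[[i]]
    lines <- c(lines, sprintf("  step %d: %s + %s", i, st$rule,
                              if (nzchar(st$participant)) st$participant
                              else "(unimolecular)"))
  }
  c(lines, sprintf("  product: %s  (E = %.3f)", route$final_smiles,
                   route$energy))
}
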