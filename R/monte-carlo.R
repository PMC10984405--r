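# --- connectivity helpers ---------------------------------------------------

# adjacency list treating each rigid body as fully connected (via a star on
# its first atom) so downstream sets carry whole subunits
.adjacency <- function(model) {
  n <- n_atoms(model)
  edges <- model$bonds
  body <- model$atoms$rigid_body
  for (bid in setdiff(unique(body), 0L)) {
    idx <- which(body == bid)
    if (length(idx) > 1) {
      edges <- rbind(edges, cbind(idx[1], idx[-1]))
    }
  }
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# atoms on the far side of the a->b bond (b's side, excluding a); errors on
# a cycle crossing back to a
.downstream_atoms <- function(adj, a, b) {
  n <- length(adj)
  visited <- logical(n)
  visited[b] <- TRUE
  queue <- b
  while (length(queue) > 0) {
    cur <- queue[[1]]
    queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (nb == a && cur == b) next
      if (nb == a) abort("Connectivity cycle crosses the rotation bond")
      if (!visited[nb]) {
        visited[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  which(visited)
}

.dihedral_axis <- function(model, segment_id, residue_number, dihedral) {
  a <- model$atoms
  sel <- which(a$segment_id == segment_id &
               a$residue_number == as.integer(residue_number))
  if (length(sel) == 0) {
    abort(sprintf("Residue %s %s not found", segment_id, residue_number))
  }
  pick <- function(nm) {
    i <- sel[a$atom_name[sel] == nm]
    if (length(i) != 1) {
      abort(sprintf("Dihedral %s undefined for %s %s: atom %s missing",
                    dihedral, segment_id, residue_number, nm))
    }
    i
  }
  if (dihedral == "phi") c(pick("N"), pick("CA")) else c(pick("CA"), pick("C"))
}

#' Rotate a backbone dihedral
#'
#' Rigidly rotates every atom downstream of the phi (N-CA) or psi (CA-C)
#' bond of the given residue about the bond axis; all other atoms are
#' unchanged, so internal geometry on both sides is preserved exactly.
#'
#' @param frame An n x 3 coordinate matrix (nm).
#' @param model The [atomic_model()] supplying topology (atom order must
#'   match `frame`).
#' @param residue List/vector with `segment_id` and `residue_number`.
#' @param dihedral `"phi"` or `"psi"`.
#' @param angle Rotation angle, degrees.
#' @return The rotated coordinate matrix.
#' @export
rotate_dihedral <- function(frame, model, residue,
                            dihedral = c("phi", "psi"), angle) {
  dihedral <- match.arg(dihedral)
  residue <- as.list(residue)
  ax <- .dihedral_axis(model, residue$segment_id, residue$residue_number,
                       dihedral)
  adj <- .adjacency(model)
  down <- .downstream_atoms(adj, ax[1], ax[2])
  .rotate_about_bond(frame, ax[1], ax[2], down, angle)
}

.rotate_about_bond <- function(frame, ia, ib, down, angle_deg) {
  u <- frame[ib, ] - frame[ia, ]
  u <- u / sqrt(sum(u^2))
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) * ct + st * K + (1 - ct) * (u %o% u)
  p0 <- frame[ia, ]
  moved <- sweep(frame[down, , drop = FALSE], 2, p0) %*% t(R)
  frame[down, ] <- sweep(moved, 2, p0, "+")
  frame
}

# --- clash detection ---------------------------------------------------------

# 1-2 and 1-3 exclusion keys ((lo-1)*n + hi - 1, 0-based, as the C++ kernel
# expects), computed once per model
.clash_context <- function(model) {
  a <- model$atoms
  n <- nrow(a)
  heavy <- which(!a$is_hydrogen)
  b <- model$bonds
  pairs <- if (nrow(b) > 0) list(b) else list()
  if (nrow(b) > 0) {
    nb <- split(c(b[, 2], b[, 1]), c(b[, 1], b[, 2]))
    for (ctr in names(nb)) {
      nbs <- unique(nb[[ctr]])
      if (length(nbs) > 1) {
        cmb <- t(utils::combn(nbs, 2))
        pairs[[length(pairs) + 1]] <- cmb
      }
    }
  }
  keys <- numeric(0)
  if (length(pairs) > 0) {
    pp <- do.call(rbind, pairs)
    lo <- pmin(pp[, 1], pp[, 2]) - 1
    hi <- pmax(pp[, 1], pp[, 2]) - 1
    keys <- unique(lo * n + hi)
  }
  list(idx = as.integer(heavy - 1L), body = as.integer(a$rigid_body),
       excl = keys)
}

#' Steric clash detection
#'
#' TRUE iff any heavy-atom pair in different rigid bodies (or involving the
#' flexible linker) is closer than `cutoff`, excluding directly bonded
#' (1-2) and angle-connected (1-3) pairs. Evaluated with a spatial cell
#' grid, so cost is near-linear in the number of atoms.
#'
#' @param frame An n x 3 coordinate matrix (nm).
#' @param model The [atomic_model()] (topology, rigid bodies, bonds).
#' @param cutoff Centre-to-centre clash distance, nm (default 0.20).
#' @param context Optional precomputed context (internal use).
#' @return Logical.
#' @export
detect_clash <- function(frame, model, cutoff = 0.20, context = NULL) {
  if (!all(is.finite(frame))) abort("coordinates must be finite")
  ctx <- context %||% .clash_context(model)
  detect_clash_cpp(frame, ctx$idx, ctx$body, ctx$excl, cutoff)
}

# --- torsion-angle Monte Carlo ----------------------------------------------

#' Torsion-angle Monte Carlo conformer sampling
#'
#' Markov-chain sampling of hinge conformations: per move, one variable
#' (residue, phi/psi) dihedral is chosen uniformly, a step-multiple angle
#' is drawn uniformly from the grid `(-180, 180]` degrees (excluding 0),
#' the rotation is applied to the current frame, and the move is accepted
#' iff the result is free of steric clashes; rejected moves revert fully.
#' Subunits declared as rigid bodies move only rigidly.
#'
#' @param model An [atomic_model()] with `rigid_body` membership.
#' @param regions Flexible regions (tibble with `segment_id`,
#'   `residue_number`, `dihedral`); defaults to `model$flexible_regions`.
#' @param n_moves Number of attempted moves.
#' @param step Angular grid step, degrees (default 15).
#' @param cutoff Clash cutoff, nm.
#' @param seed Integer seed (same seed, identical ensemble).
#' @param thin Keep every `thin`-th accepted frame (1 = all).
#' @return A `conformer_ensemble`: list with `topology`, `frames` (list of
#'   coordinate matrices), `attempted`, `accepted`, `seed`, `step`,
#'   `cutoff`.
#' @export
tamc_sample <- function(model, regions = NULL, n_moves, step = 15,
                        cutoff = 0.20, seed = 1, thin = 1) {
  stopifnot(n_moves >= 1, step > 0)
  regions <- regions %||% model$flexible_regions
  frame0 <- coords(model)
  if (is.null(regions) || nrow(regions) == 0) {
    warn("No variable dihedrals declared; returning the input conformation")
    return(structure(list(topology = model, frames = list(frame0),
                          attempted = 0L, accepted = 0L, seed = seed,
                          step = step, cutoff = cutoff),
                     class = "conformer_ensemble"))
  }
  adj <- .adjacency(model)
  moves <- purrr::pmap(regions, function(segment_id, residue_number,
                                         dihedral, ...) {
    ax <- .dihedral_axis(model, segment_id, residue_number, dihedral)
    list(ia = ax[1], ib = ax[2],
         down = .downstream_atoms(adj, ax[1], ax[2]))
  })
  ctx <- .clash_context(model)
  deltas <- setdiff(seq(-180 + step, 180, by = step), 0)
  frames <- vector("list", min(n_moves, 200000L))
  accepted <- 0L
  kept <- 0L
  cur <- frame0
  withr::with_seed(seed, {
    mv_idx <- sample.int(length(moves), n_moves, replace = TRUE)
    dl_idx <- sample.int(length(deltas), n_moves, replace = TRUE)
    for (k in seq_len(n_moves)) {
      mv <- moves[[mv_idx[k]]]
      cand <- .rotate_about_bond(cur, mv$ia, mv$ib, mv$down, deltas[dl_idx[k]])
      if (!detect_clash_cpp(cand, ctx$idx, ctx$body, ctx$excl, cutoff)) {
        accepted <- accepted + 1L
        cur <- cand
        if (accepted %% thin == 0L) {
          kept <- kept + 1L
          frames[[kept]] <- cand
        }
      }
    }
  })
  structure(list(topology = model, frames = frames[seq_len(kept)],
                 attempted = as.integer(n_moves), accepted = accepted,
                 seed = seed, step = step, cutoff = cutoff),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf(
    "<conformer_ensemble> %d moves attempted, %d accepted (%.1f%%), %d frames stored\n",
    x$attempted, x$accepted,
    if (x$attempted > 0) 100 * x$accepted / x$attempted else 0,
    length(x$frames)))
  invisible(x)
}

#' Persist an ensemble as PDB frames plus a metadata file
#'
#' @param ensemble A `conformer_ensemble`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ensemble$frames)) {
    write_pdb(set_coords(ensemble$topology, ensemble$frames[[i]]),
              file.path(dir, sprintf("frame_%06d.pdb", i)))
  }
  meta <- c(sprintf("seed %d", ensemble$seed),
            sprintf("attempted %d", ensemble$attempted),
            sprintf("accepted %d", ensemble$accepted),
            sprintf("step_deg %g", ensemble$step),
            sprintf("cutoff_nm %g", ensemble$cutoff))
  writeLines(meta, file.path(dir, "run_metadata.txt"))
  invisible(dir)
}
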