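# periodic signed distance along one box dimension
dz_periodic <- function(z, z0, L) {
  d <- z - z0
  d - L * round(d / L)
}

parse_architecture <- function(architecture) {
  toks <- regmatches(architecture, gregexpr("[HT][0-9]+", architecture))[[1]]
  if (!length(toks) || paste(toks, collapse = "") != architecture)
    stop("cannot parse architecture '", architecture,
         "' (expected e.g. H30T10, T5H10T5, H5T5)", call. = FALSE)
  blocks <- lapply(toks, function(s)
    list(species = substr(s, 1, 1), n = as.integer(substr(s, 2, nchar(s)))))
  list(blocks = blocks,
       beads = unlist(lapply(blocks, function(b) rep(b$species, b$n))),
       triblock = length(blocks) == 3 &&
         blocks[[1]]$species == "T" && blocks[[2]]$species == "H" &&
         blocks[[3]]$species == "T")
}

# z positions of the two interfaces from the instantaneous solvent density
interfaces_from_system <- function(system, bin = 1) {
  prof <- density_profile_system(system, n_bins = max(8, round(system$box[3] / bin)))
  locate_interface(prof)
}

#' Convert interfacial solvent particles into adsorbed copolymer chains
#'
#' Builds `count` block-copolymer molecules by selecting chains of adjacent
#' solvent particles in the interfacial region, connecting them with bonds and
#' changing their identity to H and T segments, so the total particle count
#' and number density are unchanged.  Chains are split evenly between the two
#' interfaces.  For liquid-vapor slabs all beads are converted W particles;
#' for liquid-liquid (W|O|W) systems the H beads are taken from the W side of
#' the interface and the T beads from the O side.  Triblock architectures
#' (e.g. `T5H10T5`) receive harmonic angles and dihedrals on the middle H
#' block, making it rigid.
#'
#' @param system A slab [particle_system()].
#' @param architecture Architecture string, e.g. `"H30T10"`, `"T5H10T5"`,
#'   `"H5T5"`.
#' @param count Number of chains.
#' @param seed Integer seed (particle selection is randomized but
#'   reproducible).
#' @param forcefield A [force_field()] supplying the bonded constants.
#' @param bond `"harmonic"` (equilibrium systems) or `"fene"` (NEMD systems).
#' @param topo Existing [topology()] to extend, or `NULL`.
#' @param neighbor_cutoff Adjacency cutoff for chain growth (sigma).
#' @param interface_halfwidth Half-width of the interfacial band from which
#'   beads are recruited (sigma).
#' @param max_retries Retries per chain before failing.
#' @return List with the modified `system` and the grown `topology`.
#' @export
insert_copolymers_by_identity_swap <- function(system, architecture, count,
                                               seed = 1L,
                                               forcefield = force_field("lv"),
                                               bond = c("harmonic", "fene"),
                                               topo = NULL,
                                               neighbor_cutoff = 1.3,
                                               interface_halfwidth = 3,
                                               max_retries = 100L) {
  bond <- match.arg(bond)
  topo <- empty_or(topo)
  if (count == 0) return(list(system = system, topology = topo))
  arch <- parse_architecture(architecture)
  L <- length(arch$beads)
  box <- system$box
  pos <- system$positions
  spc <- system$species
  mode <- if (any(spc == "O")) "ll" else "lv"
  zint <- interfaces_from_system(system)
  pairs <- cpp_neighbor_pairs(pos, box, neighbor_cutoff, 0)
  adj <- vector("list", nrow(pos))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  used <- spc %in% c("H", "T")

  # which solvent species does each bead consume?
  bead_source <- if (mode == "ll") ifelse(arch$beads == "H", "W", "O")
                 else rep("W", L)

  grow_chain <- function(iface_z) {
    in_band <- abs(dz_periodic(pos[, 3], iface_z, box[3])) < interface_halfwidth
    starts <- which(!used & spc == bead_source[1] & in_band)
    if (!length(starts)) return(NULL)
    start <- starts[sample.int(length(starts), 1)]
    sel <- integer(L)
    sel[1] <- start
    taken <- rep(FALSE, length(spc))
    taken[start] <- TRUE
    for (b in 2:L) {
      cand <- adj[[sel[b - 1]]]
      cand <- cand[!used[cand] & !taken[cand] & spc[cand] == bead_source[b] &
                   abs(dz_periodic(pos[cand, 3], iface_z, box[3])) <
                     2 * interface_halfwidth]
      if (!length(cand)) return(NULL)
      sel[b] <- cand[sample.int(length(cand), 1)]
      taken[sel[b]] <- TRUE
    }
    sel
  }

  new_bonds <- list(); new_angles <- list(); new_dih <- list()
  molecules <- topo$molecule
  with_seed(seed, {
    for (m in seq_len(count)) {
      iface <- zint[(m - 1) %% 2 + 1]
      sel <- NULL
      for (r in seq_len(max_retries)) {
        sel <- grow_chain(iface)
        if (!is.null(sel)) break
      }
      if (is.null(sel))
        stop(sprintf("chain construction failure at interface z = %.3g after %d retries",
                     iface, max_retries), call. = FALSE)
      used[sel] <- TRUE
      spc[sel] <- arch$beads
      new_bonds[[m]] <- cbind(sel[-L], sel[-1])
      if (arch$triblock) {
        h_idx <- which(arch$beads == "H")
        h <- sel[h_idx]
        if (length(h) >= 3)
          new_angles[[m]] <- cbind(h[1:(length(h) - 2)], h[2:(length(h) - 1)],
                                    h[3:length(h)])
        if (length(h) >= 4)
          new_dih[[m]] <- cbind(h[1:(length(h) - 3)], h[2:(length(h) - 2)],
                                 h[3:(length(h) - 1)], h[4:length(h)])
      }
      molecules[[length(molecules) + 1]] <- sel
    }
  })

  nb <- do.call(rbind, new_bonds)
  topo$bonds <- rbind(topo$bonds, nb)
  kind <- if (bond == "fene") 1L else 0L
  topo$bond_kind <- c(topo$bond_kind, rep(kind, nrow(nb)))
  topo$bond_k <- c(topo$bond_k,
                   rep(if (bond == "fene") forcefield$fene_k else forcefield$bond_k,
                       nrow(nb)))
  topo$bond_l0 <- c(topo$bond_l0,
                    rep(if (bond == "fene") forcefield$fene_l0 else forcefield$bond_l0,
                        nrow(nb)))
  na <- do.call(rbind, new_angles)
  if (!is.null(na)) {
    topo$angles <- rbind(topo$angles, na)
    topo$angle_k <- c(topo$angle_k, rep(forcefield$angle_k, nrow(na)))
    topo$angle_theta0 <- c(topo$angle_theta0, rep(forcefield$angle_theta0, nrow(na)))
  }
  nd <- do.call(rbind, new_dih)
  if (!is.null(nd)) {
    topo$dihedrals <- rbind(topo$dihedrals, nd)
    topo$dih_k <- c(topo$dih_k, rep(forcefield$dih_k, nrow(nd)))
    topo$dih_d <- c(topo$dih_d, rep(forcefield$dih_d, nrow(nd)))
  }
  topo$molecule <- molecules
  out <- particle_system(pos, spc, box, system$velocities,
                         slab = isTRUE(system$slab))
  list(system = out, topology = topo)
}
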