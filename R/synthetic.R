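# Synthetic fixtures with planted ground truth: torsion systems with a
# correlated relay chain, and idealized C-alpha helix-bundle ensembles with
# per-residue fluctuation amplitudes, scheduled contacts and collective modes.
# Statistical stand-ins for MD ensembles -- no force field, no sterics.

#' Sample from the von Mises distribution (degrees)
#'
#' Best-Fisher (1979) rejection sampler; used for rotamer-like torsion noise.
#'
#' @param n sample count
#' @param mu_deg mean direction in degrees
#' @param kappa concentration (> 0); 50 gives a ~10 degree spread typical of
#'   a well-defined rotamer well
#' @return angles in degrees, wrapped to `[-180, 180)`
#' @export
rvonmises <- function(n, mu_deg = 0, kappa = 50) {
  stopifnot(kappa > 0)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  need <- n
  filled <- 0L
  while (need > 0L) {
    m <- max(need + ceiling(0.15 * need), 16L)  # vectorized rejection batch
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    acc <- which(ok)
    take <- acc[seq_len(min(length(acc), need))]
    if (length(take)) {
      out[filled + seq_along(take)] <- sign(u3[take] - 0.5) * acos(f[take])
      filled <- filled + length(take)
      need <- n - filled
    }
  }
  wrap_angle(mu_deg + out * 180 / pi)
}

#' Specification of a synthetic torsion system
#'
#' A hidden two-state symmetric Markov chain (flip probability
#' `flip_prob`/frame) drives an ordered relay of residues: each relay residue
#' follows the latent state with probability `coupling` per frame (otherwise
#' it draws an independent state), and emits chi1 = vonMises(center[state],
#' kappa). Background residues run their own independent two-state chains.
#' Defaults emulate rotamer switching between gauche- (-60) and trans (180).
#'
#' @param n_residues total residue count
#' @param n_frames frame count
#' @param relay ordered residue indices forming the relay chain
#' @param coupling coupling strength c in [0, 1]
#' @param kappa von Mises concentration, default 50
#' @param flip_prob latent-state flip probability per frame, default 0.02
#' @param centers two state centers in degrees, default c(-60, 180)
#' @param seed RNG seed
#' @return a `torsion_system_spec`
#' @export
torsion_system_spec <- function(n_residues = 60, n_frames = 5000,
                                relay = 1:8, coupling = 0.9, kappa = 50,
                                flip_prob = 0.02, centers = c(-60, 180),
                                seed = 1) {
  if (anyDuplicated(relay) || any(relay < 1) || any(relay > n_residues))
    stopf("relay indices must be distinct and within 1..n_residues")
  if (coupling < 0 || coupling > 1) stopf("coupling must be in [0, 1]")
  if (kappa <= 0) stopf("kappa must be > 0")
  structure(list(n_residues = n_residues, n_frames = n_frames, relay = relay,
                 coupling = coupling, kappa = kappa, flip_prob = flip_prob,
                 centers = centers, seed = seed),
            class = "torsion_system_spec")
}

two_state_chain <- function(n, flip_prob, u) {
  s <- integer(n)
  s[1] <- as.integer(u[1] < 0.5)
  flips <- u[-1] < flip_prob
  s[-1] <- (s[1] + cumsum(flips)) %% 2L
  s
}

#' Generate a synthetic torsion system with a planted relay
#'
#' All randomness flows from `spec$seed`; the caller's RNG state is left
#' untouched. Random draws are laid out so that regenerating with a different
#' `coupling` but the same seed reuses the same latent chain, corruption
#' uniforms and angular deviations (common random numbers), making relay MI
#' monotone in the coupling by construction.
#'
#' @param spec a [torsion_system_spec()]
#' @return list with `torsions` (a `torsion_set`, one chi1 series per
#'   residue, keys `"A:i"`) and `truth` (relay keys, expected high-MI pairs,
#'   per-frame latent states, the spec)
#' @export
generate_torsion_system <- function(spec) {
  stopifnot(inherits(spec, "torsion_system_spec"))
  nr <- spec$n_residues; nf <- spec$n_frames
  with_seed(spec$seed, {
    u_latent <- stats::runif(nf)
    latent <- two_state_chain(nf, spec$flip_prob, u_latent)
    u_follow <- matrix(stats::runif(nr * nf), nr, nf)
    u_indep <- matrix(stats::runif(nr * nf), nr, nf)
    dev <- matrix(rvonmises(nr * nf, 0, spec$kappa), nr, nf)
    u_bg <- matrix(stats::runif(nr * nf), nr, nf)
    series <- vector("list", nr)
    is_relay <- seq_len(nr) %in% spec$relay
    for (i in seq_len(nr)) {
      state <- if (is_relay[i]) {
        ifelse(u_follow[i, ] < spec$coupling, latent,
               as.integer(u_indep[i, ] < 0.5))
      } else {
        two_state_chain(nf, spec$flip_prob, u_bg[i, ])
      }
      series[[i]] <- wrap_angle(spec$centers[state + 1L] + dev[i, ])
    }
    keys <- res_key("A", seq_len(nr))
    names(series) <- paste0(keys, "|chi1")
    relay_keys <- keys[spec$relay]
    truth <- list(
      relay = relay_keys,
      high_mi_pairs = if (length(spec$relay) > 1)
        cbind(relay_keys[-length(relay_keys)], relay_keys[-1]) else NULL,
      latent = latent, spec = spec)
    list(torsions = new_torsion_set(series, keys, nf), truth = truth)
  })
}

# ---- Cartesian helix-bundle ensembles --------------------------------------

#' Specification of a synthetic C-alpha ensemble
#'
#' The reference is an idealized C-alpha helix bundle (1.5 Angstrom rise and
#' 100 degrees rotation per residue, helix radius 2.3 Angstrom) with helix
#' axes on a circle wide enough that inter-helix spacing is >= 10 Angstrom.
#' Frames add per-residue isotropic Gaussian jitter `sigma`, scheduled
#' contact-former displacements, and an optional collective mode.
#'
#' @param n_helices helix count, default 2
#' @param helix_length residues per helix, default 30
#' @param n_frames frame count, default 100
#' @param sigma per-residue fluctuation amplitude (Angstrom); scalar or
#'   length `n_helices * helix_length`
#' @param contact_schedule list of `list(a = residue-index, b =
#'   residue-index, frames = frame-index-vector)`: in scheduled frames
#'   residue `b` is moved to 4 Angstrom from residue `a` (in contact at the
#'   default 4.5 criterion), otherwise both stay at reference
#' @param mode_vector optional planted collective mode, a `3N` vector (or
#'   NULL); applied as `amplitude * sin(2 pi t / n_frames) * mode`
#' @param mode_amplitude amplitude in Angstrom, default 3
#' @param bundle_spacing center-to-center helix spacing, >= 10, default 12
#' @param seed RNG seed
#' @return a `cartesian_system_spec`
#' @export
cartesian_system_spec <- function(n_helices = 2, helix_length = 30,
                                  n_frames = 100, sigma = 0.3,
                                  contact_schedule = list(),
                                  mode_vector = NULL, mode_amplitude = 3,
                                  bundle_spacing = 12, seed = 1) {
  n_res <- n_helices * helix_length
  if (length(sigma) == 1) sigma <- rep(sigma, n_res)
  if (length(sigma) != n_res) stopf("sigma must be scalar or length %d", n_res)
  if (any(sigma < 0)) stopf("sigma must be >= 0")
  for (cs in contact_schedule) {
    if (!all(c("a", "b", "frames") %in% names(cs)))
      stopf("contact_schedule entries need fields a, b, frames")
    if (any(cs$frames < 1) || any(cs$frames > n_frames))
      stopf("contact schedule references frames outside 1..n_frames")
    if (cs$a < 1 || cs$a > n_res || cs$b < 1 || cs$b > n_res)
      stopf("contact schedule references residues outside the bundle")
  }
  if (!is.null(mode_vector) && length(mode_vector) != 3 * n_res)
    stopf("mode_vector must have length 3 * n_residues")
  if (bundle_spacing < 10) stopf("bundle_spacing must be >= 10")
  structure(list(n_helices = n_helices, helix_length = helix_length,
                 n_frames = n_frames, sigma = sigma,
                 contact_schedule = contact_schedule,
                 mode_vector = mode_vector, mode_amplitude = mode_amplitude,
                 bundle_spacing = bundle_spacing, seed = seed),
            class = "cartesian_system_spec")
}

ideal_helix_ca <- function(n, origin = c(0, 0, 0)) {
  t <- (seq_len(n) - 1)
  cbind(origin[1] + 2.3 * cos(t * 100 * pi / 180),
        origin[2] + 2.3 * sin(t * 100 * pi / 180),
        origin[3] + 1.5 * t)
}

#' Generate a synthetic C-alpha ensemble with planted ground truth
#'
#' @param spec a [cartesian_system_spec()]
#' @return list with `model` (reference `structure_model`, chains A, B, ...
#'   one per helix, CA atoms only), `traj` (a `trajectory`), and `truth`
#'   (per-residue sigma, contact occupancies in percent, planted mode)
#' @export
generate_cartesian_system <- function(spec) {
  stopifnot(inherits(spec, "cartesian_system_spec"))
  nh <- spec$n_helices; hl <- spec$helix_length
  n_res <- nh * hl; nf <- spec$n_frames
  ring_r <- if (nh == 1) 0 else spec$bundle_spacing / (2 * sin(pi / nh))
  ref <- NULL
  chains <- character(0)
  for (h in seq_len(nh)) {
    ang <- 2 * pi * (h - 1) / nh
    ref <- rbind(ref, ideal_helix_ca(hl, c(ring_r * cos(ang),
                                           ring_r * sin(ang), 0)))
    chains <- c(chains, rep(LETTERS[h], hl))
  }
  resid <- rep(seq_len(hl), nh)
  atoms <- data.frame(
    serial = seq_len(n_res), name = "CA", altloc = " ", resname = "ALA",
    chain = chains, resid = resid, icode = "",
    x = ref[, 1], y = ref[, 2], z = ref[, 3],
    occupancy = 1, element = "C", stringsAsFactors = FALSE)
  model <- new_structure_model(atoms)
  coords <- with_seed(spec$seed, {
    arr <- array(rep(ref, nf), dim = c(n_res, 3, nf))
    jitter <- array(stats::rnorm(n_res * 3 * nf), dim = c(n_res, 3, nf)) *
      spec$sigma
    arr <- arr + jitter
    if (!is.null(spec$mode_vector)) {
      mv <- matrix(spec$mode_vector, ncol = 3, byrow = TRUE)
      for (f in seq_len(nf))
        arr[, , f] <- arr[, , f] +
          spec$mode_amplitude * sin(2 * pi * f / nf) * mv
    }
    for (cs in spec$contact_schedule) {
      # place b 4 A from a, radially outward from a's helix axis: far from
      # a's helical neighbors, so exactly the scheduled pair is in contact
      ha <- ceiling(cs$a / hl)
      ang_a <- 2 * pi * (ha - 1) / nh
      ctr <- c(ring_r * cos(ang_a), ring_r * sin(ang_a))
      rad <- c(ref[cs$a, 1:2] - ctr, 0)
      rad <- rad / sqrt(sum(rad^2))
      for (f in cs$frames)
        arr[cs$b, , f] <- arr[cs$a, , f] + 4.0 * rad
    }
    arr
  })
  occ <- lapply(spec$contact_schedule, function(cs) list(
    a = model$atoms$reskey[cs$a], b = model$atoms$reskey[cs$b],
    occupancy = 100 * length(cs$frames) / nf))
  truth <- list(sigma = spec$sigma, contacts = occ,
                mode_vector = spec$mode_vector, spec = spec)
  list(model = model, traj = new_trajectory(model, coords), truth = truth)
}

# ---- Internal-coordinate peptide builder (NeRF) ----------------------------

# Place atom D given A, B, C and (bond CD, angle BCD deg, torsion ABCD deg).
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m2 + d2[3] * n
}

#' Build a polypeptide backbone from torsion angles
#'
#' Places N, CA, C (and O) atoms with standard bond geometry from supplied
#' phi/psi (omega fixed at 180). Optionally adds CB and CG atoms so chi1 is
#' defined, in which case residues are named LEU (chi2 atoms absent and
#' skipped by torsion extraction). Useful for fixtures where the planted
#' torsions must be recovered exactly by [extract_torsions()].
#'
#' @param phi,psi numeric vectors of equal length n (degrees); `phi[1]` and
#'   `psi[n]` are ignored (undefined at the termini)
#' @param chi1 optional chi1 angles (degrees) to plant, or NULL for backbone
#'   only
#' @param chain chain id, default "A"
#' @return a `structure_model`
#' @export
build_peptide <- function(phi, psi, chi1 = NULL, chain = "A") {
  n <- length(phi)
  stopifnot(length(psi) == n, is.null(chi1) || length(chi1) == n)
  # seed first residue
  N1 <- c(0, 0, 0)
  CA1 <- c(1.458, 0, 0)
  C1 <- CA1 + 1.525 * c(cos(pi - 111.2 * pi / 180),
                        sin(pi - 111.2 * pi / 180), 0)
  pos <- list()
  pos[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (i in seq_len(n)) {
    if (i > 1) {
      prevv <- pos[[i - 1]]
      Ni <- nerf_place(prevv$N, prevv$CA, prevv$C, 1.329, 116.2, psi[i - 1])
      CAi <- nerf_place(prevv$CA, prevv$C, Ni, 1.458, 121.7, 180)
      Ci <- nerf_place(prevv$C, Ni, CAi, 1.525, 111.2, phi[i])
      pos[[i]] <- list(N = Ni, CA = CAi, C = Ci)
    }
    p <- pos[[i]]
    # carbonyl O off the C, trans to the next N direction (approximate)
    pos[[i]]$O <- nerf_place(p$N, p$CA, p$C, 1.231, 120.5,
                             wrap_angle((if (i < n) psi[i] else 0) + 180))
    if (!is.null(chi1)) {
      pos[[i]]$CB <- nerf_place(p$C, p$N, p$CA, 1.53, 110.5, 122.5)
      pos[[i]]$CG <- nerf_place(p$N, p$CA, pos[[i]]$CB, 1.53, 114, chi1[i])
    }
  }
  rows <- list()
  serial <- 0L
  resname <- if (is.null(chi1)) "GLY" else "LEU"
  for (i in seq_len(n)) for (an in names(pos[[i]])) {
    serial <- serial + 1L
    xyz <- pos[[i]][[an]]
    rows[[serial]] <- data.frame(
      serial = serial, name = an, altloc = " ", resname = resname,
      chain = chain, resid = i, icode = "", x = xyz[1], y = xyz[2],
      z = xyz[3], occupancy = 1,
      element = substr(an, 1, 1), stringsAsFactors = FALSE)
  }
  new_structure_model(do.call(rbind, rows))
}
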