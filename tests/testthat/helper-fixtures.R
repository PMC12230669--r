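# Fixture builders: tiny hand-placed structures and an identity mapping,
# plus independent oracles used across tests.

# structure with one CA atom per residue from a coordinate table
# coords: data.frame(chain, resno, x, y, z) — resid defaults to ALA
st_from_ca <- function(coords, label = "toy", resid = "ALA") {
  atoms <- data.frame(
    chain = coords$chain, resno = coords$resno, ins = "",
    resid = resid, atom = "CA", element = "C",
    x = coords$x, y = coords$y, z = coords$z, b = 0,
    stringsAsFactors = FALSE
  )
  structure3d(atoms, label = label)
}

# identity chain mapping for a structure (model == reference layout)
identity_mapping <- function(s) {
  keys <- residue_keys(s)
  rm_ <- keys
  names(rm_) <- keys
  ch <- chain_ids(s)
  chains <- ch
  names(chains) <- ch
  structure(list(chains = chains, res_map = rm_,
                 shared_contacts = NA_integer_, groups = NULL),
            class = "chain_mapping")
}

# manual mapping between two structures with identical layouts
manual_mapping <- function(model, reference) {
  km <- residue_keys(model)
  kr <- residue_keys(reference)
  stopifnot(length(km) == length(kr))
  rm_ <- kr
  names(rm_) <- km
  cm <- chain_ids(reference)
  names(cm) <- chain_ids(model)
  structure(list(chains = cm, res_map = rm_,
                 shared_contacts = NA_integer_, groups = NULL),
            class = "chain_mapping")
}

# random proper rotation from a seeded stream
random_rotation <- function() {
  axis <- stats::rnorm(3)
  dockjury:::rotation_about_axis(axis, stats::runif(1, 0, 360))
}

# independent quaternion (Horn) superposition oracle: minimal RMSD of Q
# onto P via the eigenvector of the 4x4 characteristic matrix
quaternion_rmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(Pc, Qc)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(Pc^2) + sum(Qc^2) - 2 * lambda) / nrow(P)
  sqrt(max(0, msd))
}

# brute-force AUC by explicit pair enumeration
auc_brute <- function(pred, obs, at = 0.5) {
  ok <- !is.na(pred) & !is.na(obs)
  pred <- pred[ok]; lab <- obs[ok] >= at
  pos <- pred[lab]; neg <- pred[!lab]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# a small A2 dimer pool pair for randomized property tests
dimer_and_decoy <- function(seed, sigma = 0.5) {
  spec <- decoy_spec("A2", chain_length = 8, seed = seed)
  ref <- make_reference(spec)
  dec <- perturb(ref, "B", rotation = stats::runif(1, 0, 30),
                 translation = stats::runif(1, 0, 4), noise = sigma,
                 seed = seed)
  list(ref = ref, dec = dec)
}
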