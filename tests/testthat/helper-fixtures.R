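# shared helpers: all fixtures are built in code at test time

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# a generic (non-degenerate) random pair without the generator's rigid motion
random_cloud_pair <- function(n, seed, spread = 6, noise = 1) {
  with_seed(seed, {
    a <- matrix(runif(3 * n, -spread, spread), ncol = 3)
    b <- a + matrix(rnorm(3 * n, sd = noise), ncol = 3)
    pair_structures(protein_structure(a), protein_structure(b))
  })
}

random_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# random anchored frame with exact chord congruence
random_frame <- function(pair, seed) {
  with_seed(seed, {
    kl <- sample(pair$n, 2L)
    r <- sqrt(sum((pair$model$xyz[kl[2], ] - pair$model$xyz[kl[1], ])^2))
    image_k <- rnorm(3, sd = 4)
    image_l <- image_k + r * random_unit()
    anchored_transform(pair, kl[1], kl[2], image_k, image_l)
  })
}

# independent dense-scan oracle for the best axis rotation
dense_scan_max <- function(pair, frame, cutoff, n_angles = 1e4) {
  axis_dir <- frame$image_l - frame$image_k
  axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
  angles <- (seq_len(n_angles) - 1) * 2 * pi / n_angles
  best <- 0L
  pts <- apply_transform(frame$base_transform, pair$model$xyz)
  # closed-form squared distance per angle, vectorized over residues
  u <- axis_dir
  d <- sweep(pts, 2, frame$image_k)
  alpha <- as.numeric(d %*% u)
  e <- d - outer(alpha, u)
  rho <- sqrt(rowSums(e^2))
  w <- sweep(pair$target$xyz, 2, frame$image_k) - outer(alpha, u)
  wpar <- as.numeric(w %*% u)
  wperp <- w - outer(wpar, u)
  q <- sqrt(rowSums(wperp^2))
  A <- wpar^2 + q^2 + rho^2
  B <- 2 * rho * q
  e1 <- gdtarea:::perpendicular_unit(u)
  e2 <- gdtarea:::cross3(u, e1)
  phip <- atan2(e %*% e2, e %*% e1)
  phit <- atan2(wperp %*% e2, wperp %*% e1)
  centre <- as.numeric(phit) - as.numeric(phip)
  c2 <- (cutoff + 1e-9)^2
  for (phi in angles) {
    d2 <- A - B * cos(phi - centre)
    cnt <- sum(d2 <= c2)
    if (cnt > best) best <- cnt
  }
  best
}

# minimal hand-written PDB ATOM records
pdb_atom_line <- function(serial, resno, x, y, z, chain = "A", alt = " ",
                          occ = 1.00, elety = " CA ", resid = "ALA",
                          icode = " ") {
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, elety, alt, resid, chain, resno, icode, x, y, z, occ, 0)
}

write_test_pdb <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}
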