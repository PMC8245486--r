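# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdir().

# Minimal hand-built CFU table: one worm pair condition plus its monocultures.
toy_pair_table <- function(counts_i = c(100, 120, 80, 100),
                           counts_j = c(300, 280, 320, 300),
                           mono_i = c(200, 180, 220),
                           mono_j = c(400, 380, 420),
                           sp = c("Ea", "Pf"), host = "AU37") {
  n <- length(counts_i)
  rbind(
    data.frame(environment = "worm", host_strain = host,
               community = paste(sort(sp), collapse = ";"),
               species_id = rep(sp, each = n),
               replicate = rep(seq_len(n), 2),
               count = c(counts_i, counts_j), unit = "cfu_per_worm",
               stringsAsFactors = FALSE),
    data.frame(environment = "worm", host_strain = host,
               community = sp[1], species_id = sp[1],
               replicate = seq_along(mono_i), count = mono_i,
               unit = "cfu_per_worm", stringsAsFactors = FALSE),
    data.frame(environment = "worm", host_strain = host,
               community = sp[2], species_id = sp[2],
               replicate = seq_along(mono_j), count = mono_j,
               unit = "cfu_per_worm", stringsAsFactors = FALSE))
}

# Competition matrix built directly from a full F matrix (complementary).
toy_competition_matrix <- function(Fm, sem = NULL, n = 4) {
  ids <- rownames(Fm)
  stopifnot(!is.null(ids))
  diag(Fm) <- NA_real_
  if (is.null(sem)) {
    sem <- matrix(0.01, nrow(Fm), ncol(Fm), dimnames = dimnames(Fm))
    diag(sem) <- NA_real_
  }
  structure(list(species_ids = ids, F = Fm, sem = sem,
                 n = matrix(n, nrow(Fm), ncol(Fm), dimnames = dimnames(Fm)),
                 source = "toy"),
            class = "competition_matrix")
}

# Random complementary F matrix with named species.
random_F_matrix <- function(n, seed = 1) {
  set.seed(seed)
  ids <- sprintf("s%02d", seq_len(n))
  Fm <- matrix(0.5, n, n, dimnames = list(ids, ids))
  up <- upper.tri(Fm)
  Fm[up] <- runif(sum(up))
  Fm[lower.tri(Fm)] <- 1 - t(Fm)[lower.tri(Fm)]
  diag(Fm) <- NA_real_
  Fm
}

# Outcome table straight from a classified F matrix (no replicates).
outcomes_from_F <- function(Fm, threshold = 0.02) {
  ids <- rownames(Fm)
  pairs <- utils::combn(ids, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    f <- c(Fm[i, j], Fm[j, i]); names(f) <- c(i, j)
    cl <- classify_pair(f, threshold)
    data.frame(species_i = i, species_j = j, environment = "worm",
               host_strain = "AU37", f_i = f[[1]], f_j = f[[2]],
               sem_i = NA_real_, sem_j = NA_real_, n_replicates = 1L,
               category = cl$category, excluded = cl$excluded,
               override_applied = FALSE, note = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
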