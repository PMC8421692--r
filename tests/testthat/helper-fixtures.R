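# Small hand-made cohort: 8 controls + a few patients, covariates varied.
make_test_cohort <- function() {
  cohort_table(data.frame(
    participant_id = sprintf("p%02d", 1:14),
    group = c(rep("control", 8), "scd", "scd", "mci", "mci",
              "dementia", "dementia"),
    age = c(65, 70, 72, 68, 75, 80, 62, 71, 66, 73, 74, 69, 77, 78),
    sex = c("female", "male", "female", "male", "female", "male",
            "female", "male", "female", "male", "female", "male",
            "female", "male"),
    education = c(12, 14, 10, 16, 8, 11, 15, 13, 12, 9, 10, 14, 7, 11),
    mmse = c(29, 30, 28, 29, 30, 28, 29, 30, 29, 28, 26, 27, 21, 19),
    smd_raw = c(8, 6, 10, 7, 12, 9, 5, 11, 15, 13, 14, 16, 17, 15),
    objmem_raw = c(12, 13, 11, 14, 10, 12, 13, 11, 11, 12, 7, 6, 3, 2),
    stringsAsFactors = FALSE
  ))
}

# Independent connected-component oracle: adjacency by coordinate differences,
# components via boolean transitive closure of the adjacency matrix (a
# different algorithm and representation from the package's BFS labelling).
oracle_components <- function(binary, connectivity) {
  coords <- which(binary > 0, arr.ind = TRUE)
  n <- nrow(coords)
  if (n == 0L) return(list(membership = integer(0), sizes = integer(0)))
  adj <- matrix(FALSE, n, n)
  for (a in seq_len(n)) {
    d <- abs(sweep(coords, 2L, coords[a, ], "-"))
    chebyshev <- apply(d, 1L, max)
    manhattan <- rowSums(d)
    nb <- switch(as.character(connectivity),
                 "6" = manhattan == 1L,
                 "18" = chebyshev == 1L & manhattan <= 2L,
                 "26" = chebyshev == 1L)
    adj[a, ] <- nb
  }
  reach <- adj | diag(n) > 0
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  membership <- integer(n)
  lab <- 0L
  for (a in seq_len(n)) {
    if (membership[a] == 0L) {
      lab <- lab + 1L
      membership[reach[a, ]] <- lab
    }
  }
  list(membership = membership, sizes = as.integer(table(membership)),
       coords = coords)
}

# brute-force per-voxel OLS oracle: beta and t for one design column
oracle_voxel_fit <- function(y, X, target_col) {
  fit <- lm(y ~ X - 1)
  ct <- summary(fit)$coefficients
  rn <- paste0("X", colnames(X))
  c(beta = unname(ct[rn[target_col], 1]), t = unname(ct[rn[target_col], 3]))
}

make_stack <- function(data4, mask = NULL, ids = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(data4)[2:4])
  if (is.null(ids)) ids <- sprintf("p%02d", seq_len(dim(data4)[1]))
  volume_stack(data4, mask, ids)
}
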