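#' Simulate a simple breeding pedigree
#'
#' Founder sires and dams are mated in a round-robin design (each dam to one
#' sire, sires reused across dams), producing full-sib litters; subsequent
#' generations repeat the design using offspring of the previous generation
#' as parents. The result is acyclic with parents preceding offspring.
#'
#' @param n_sires,n_dams founder counts per generation (>= 1).
#' @param offspring_per_pair litter size per mating pair.
#' @param generations number of offspring generations.
#' @param seed optional integer seed (offspring sexes are random).
#' @return `data.table` with columns `id`, `sire`, `dam`, `sex`
#'   ("M"/"F"), `generation`; founder parents are `NA`.
#' @export
simulate_pedigree <- function(n_sires, n_dams, offspring_per_pair,
                              generations = 1, seed = NULL) {
  stopifnot(n_sires >= 1, n_dams >= 1, offspring_per_pair >= 1,
            generations >= 1)
  with_seed(seed, {
    ped <- data.table(
      id = c(sprintf("S0_%d", seq_len(n_sires)),
             sprintf("D0_%d", seq_len(n_dams))),
      sire = NA_character_, dam = NA_character_,
      sex = rep(c("M", "F"), c(n_sires, n_dams)),
      generation = 0L)
    sires <- ped[sex == "M", id]; dams <- ped[sex == "F", id]
    for (g in seq_len(generations)) {
      pair_sire <- sires[(seq_along(dams) - 1L) %% length(sires) + 1L]
      off <- rbindlist(lapply(seq_along(dams), function(i)
        data.table(
          id = sprintf("G%d_%d_%d", g, i, seq_len(offspring_per_pair)),
          sire = pair_sire[i], dam = dams[i],
          sex = sample(c("M", "F"), offspring_per_pair, replace = TRUE),
          generation = g)))
      ped <- rbind(ped, off)
      if (g < generations) {
        sires <- off[sex == "M", id]; dams <- off[sex == "F", id]
        if (!length(sires) || !length(dams))
          stop("a generation produced no offspring of one sex; ",
               "increase offspring_per_pair")
      }
    }
    ped[]
  })
}

# Topological order of a pedigree (parents before offspring); errors on
# cycles or parents missing from the id column.
pedigree_order <- function(ped) {
  ped <- as.data.table(ped)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  parent_idx <- cbind(idx[ped$sire], idx[ped$dam])
  known <- !is.na(ped$sire) & is.na(parent_idx[, 1L])
  if (any(known)) stop("sire(s) not in pedigree: ",
                       paste(head(ped$sire[known]), collapse = ", "))
  known <- !is.na(ped$dam) & is.na(parent_idx[, 2L])
  if (any(known)) stop("dam(s) not in pedigree: ",
                       paste(head(ped$dam[known]), collapse = ", "))
  placed <- logical(n); ord <- integer(n); k <- 0L
  repeat {
    ready <- !placed &
      (is.na(parent_idx[, 1L]) | placed[parent_idx[, 1L]]) &
      (is.na(parent_idx[, 2L]) | placed[parent_idx[, 2L]])
    if (!any(ready)) break
    w <- which(ready)
    ord[k + seq_along(w)] <- w
    k <- k + length(w)
    placed[w] <- TRUE
  }
  if (k < n) stop("pedigree is cyclic or inconsistent")
  ord
}
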