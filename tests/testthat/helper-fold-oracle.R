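# Brute-force folding oracle, independent of the package's DP engine:
# enumerates every non-crossing set of canonical pairs and scores it with
# its own copy of the documented energy constants.

oracle_pair_type <- function(a, b) {
  types <- c(AU = 1, UA = 2, GC = 3, CG = 4, GU = 5, UG = 6)
  key <- paste0(a, b)
  if (key %in% names(types)) types[[key]] else 0
}
oracle_pair_strength <- c(-2.1, -2.1, -3.3, -3.3, -1.4, -1.4)

oracle_enum_structures <- function(ch, i, j, min_h = 3) {
  if (j - i < min_h + 1) return(list(matrix(integer(0), ncol = 2)))
  out <- list()
  for (s in oracle_enum_structures(ch, i + 1, j, min_h)) {
    out[[length(out) + 1]] <- s
  }
  for (k in (i + min_h + 1):j) {
    if (oracle_pair_type(ch[i], ch[k]) == 0) next
    left <- oracle_enum_structures(ch, i + 1, k - 1, min_h)
    right <- if (k + 1 <= j) oracle_enum_structures(ch, k + 1, j, min_h)
    else list(matrix(integer(0), ncol = 2))
    for (a in left) for (b in right) {
      out[[length(out) + 1]] <- rbind(matrix(c(i, k), ncol = 2), a, b)
    }
  }
  out
}

oracle_structure_energy <- function(ch, pairs, min_h = 3) {
  if (nrow(pairs) == 0) return(0)
  n <- length(ch)
  mate <- integer(n)
  for (r in seq_len(nrow(pairs))) {
    mate[pairs[r, 1]] <- pairs[r, 2]
    mate[pairs[r, 2]] <- pairs[r, 1]
  }
  e <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    kids <- matrix(integer(0), ncol = 2)
    u <- 0L
    p <- i + 1L
    while (p < j) {
      if (mate[p] > p) {
        kids <- rbind(kids, c(p, mate[p]))
        p <- mate[p] + 1L
      } else {
        u <- u + 1L
        p <- p + 1L
      }
    }
    c_n <- nrow(kids)
    if (c_n == 0) {
      e <- e + 3.5 + 0.3 * (u - min_h)                       # hairpin
    } else if (c_n == 1) {
      k <- kids[1, 1]; l <- kids[1, 2]
      s1 <- k - i - 1L; s2 <- j - l - 1L
      if (s1 == 0 && s2 == 0) {                              # stack
        e <- e + 0.5 * (oracle_pair_strength[oracle_pair_type(ch[i], ch[j])] +
                          oracle_pair_strength[oracle_pair_type(ch[k], ch[l])])
      } else if (s1 == 0 || s2 == 0) {                       # bulge
        e <- e + 3.0 + 0.3 * (s1 + s2)
      } else {                                               # internal
        e <- e + 2.5 + 0.3 * (s1 + s2)
      }
    } else {                                                 # multiloop
      e <- e + 3.4 + 0.4 * (c_n + 1) + 0.1 * u
    }
  }
  e
}

oracle_mfe <- function(seq) {
  ch <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  structs <- oracle_enum_structures(ch, 1L, length(ch))
  min(vapply(structs, function(p) oracle_structure_energy(ch, p), numeric(1)))
}
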