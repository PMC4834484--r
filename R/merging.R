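# Unique-reflection enumeration under Laue class 4/mmm, Monte Carlo
# merging of still-pattern intensities, and half-set data-quality
# statistics (R_split, CC1/2, completeness).

# The 16 point-group operations of 4/mmm (including Friedel inversion),
# built once by closure from generators (4-fold about c, 2-fold about a,
# inversion) acting on Miller indices.
.laue_ops_4mmm <- local({
  r4 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  r2 <- matrix(c(1, 0, 0, 0, -1, 0, 0, 0, -1), 3, 3, byrow = TRUE)
  inv <- -diag(3)
  ops <- list(diag(3))
  repeat {
    new <- list()
    for (o in ops) for (g in list(r4, r2, inv)) {
      cand <- o %*% g
      key <- paste(cand, collapse = ",")
      known <- vapply(c(ops, new), function(x) paste(x, collapse = ",") == key,
                      logical(1))
      if (!any(known)) new <- c(new, list(cand))
    }
    if (!length(new)) break
    ops <- c(ops, new)
  }
  stopifnot(length(ops) == 16L)
  ops
})

.check_laue <- function(laue_group) {
  if (!identical(laue_group, "4/mmm")) {
    stop("unsupported Laue group: ", laue_group)
  }
}

#' Canonical (symmetry-reduced) Miller indices under 4/mmm
#'
#' Applies the 16 point-group operations of Laue class 4/mmm (Friedel
#' inversion included) and returns the lexicographically greatest
#' equivalent of each index triple. The map is idempotent, so two
#' reflections are symmetry-equivalent iff their canonical triples match.
#'
#' @param hkl Integer vector of length 3, or an `n x 3` integer matrix.
#' @param laue_group Laue class label; only `"4/mmm"` is supported.
#' @return Same shape as the input, canonicalised.
#' @examples
#' canonical_hkl(c(-1, -2, -3))  # (2, 1, 3)
#' @export
canonical_hkl <- function(hkl, laue_group = "4/mmm") {
  .check_laue(laue_group)
  vec <- !is.matrix(hkl)
  m <- if (vec) matrix(as.integer(hkl), 1L, 3L) else {
    storage.mode(hkl) <- "integer"
    hkl
  }
  if (ncol(m) != 3L) stop("hkl must have 3 columns")
  if (any(rowSums(m == 0L) == 3L)) stop("(0,0,0) has no canonical form")
  B <- max(abs(m)) + 1L
  enc <- function(x) ((x[, 1] + B) * (2 * B + 1) + (x[, 2] + B)) * (2 * B + 1) +
    (x[, 3] + B)
  best <- m
  best_key <- enc(m)
  for (op in .laue_ops_4mmm) {
    cand <- m %*% t(op)
    storage.mode(cand) <- "integer"
    key <- enc(cand)
    better <- key > best_key
    if (any(better)) {
      best[better, ] <- cand[better, , drop = FALSE]
      best_key[better] <- key[better]
    }
  }
  if (vec) as.integer(best[1L, ]) else best
}

# d-spacing of (h,k,l) in a tetragonal cell.
.d_tetragonal <- function(h, k, l, a, c) {
  1 / sqrt((h^2 + k^2) / a^2 + l^2 / c^2)
}

#' Enumerate unique reflections in a resolution range
#'
#' Lists one representative per 4/mmm symmetry orbit with `d_min <= d <=
#' d_max` (inclusive at both ends) for a tetragonal cell, where
#' `d = 1 / sqrt((h^2 + k^2)/a^2 + l^2/c^2)`. Systematically absent
#' reflections of P4\out{<sub>3</sub>}2\out{<sub>1</sub>}2 (00l with l != 4n; h00 with odd h) are
#' excluded by default, which reproduces the unique-reflection counts of
#' merged SFX data sets for this space group; set `include_absences = TRUE`
#' to count all lattice points regardless.
#'
#' @param cell Numeric length-6 tetragonal cell (a, b, c, angles 90).
#' @param laue_group Only `"4/mmm"`.
#' @param d_max,d_min Resolution limits in Å (`d_max > d_min > 0`).
#' @param include_absences Count systematically absent reflections too
#'   (default `FALSE`).
#' @return `unique_reflections`: `data.frame` with columns `h`, `k`, `l`
#'   (canonical representatives, `h >= k >= 0`, `l >= 0`) and `d`.
#'   `count_unique` returns just the row count.
#' @export
unique_reflections <- function(cell, laue_group = "4/mmm", d_max, d_min,
                               include_absences = FALSE) {
  .check_laue(laue_group)
  cell <- as.numeric(cell)
  if (length(cell) != 6L || !isTRUE(all.equal(cell[1], cell[2])) ||
      !isTRUE(all.equal(cell[4:6], c(90, 90, 90)))) {
    stop("only tetragonal cells are supported (a = b, angles 90)")
  }
  if (!(d_max > d_min) || d_min <= 0) stop("need d_max > d_min > 0")
  a <- cell[1]; c_ <- cell[3]
  hmax <- floor(a / d_min)
  lmax <- floor(c_ / d_min)
  # asymmetric unit of 4/mmm: h >= k >= 0, l >= 0
  grid <- expand.grid(h = 0:hmax, k = 0:hmax, l = 0:lmax,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$h >= grid$k & !(grid$h == 0L & grid$k == 0L & grid$l == 0L), ]
  d <- .d_tetragonal(grid$h, grid$k, grid$l, a, c_)
  sel <- d >= d_min & d <= d_max
  grid <- grid[sel, ]
  d <- d[sel]
  if (!include_absences) {
    keep <- !.is_absent_p43212(grid$h, grid$k, grid$l)
    grid <- grid[keep, ]
    d <- d[keep]
  }
  out <- data.frame(h = as.integer(grid$h), k = as.integer(grid$k),
                    l = as.integer(grid$l), d = d)
  out[order(-out$d, out$h, out$k, out$l), ]
}

#' @rdname unique_reflections
#' @export
count_unique <- function(cell, laue_group = "4/mmm", d_max, d_min,
                         include_absences = FALSE) {
  nrow(unique_reflections(cell, laue_group, d_max, d_min, include_absences))
}

.hkl_key <- function(h, k, l) paste(h, k, l)

#' Monte Carlo merge of reflection observations
#'
#' Reduces each observation's indices to the canonical 4/mmm
#' representative and averages all observations of each unique reflection
#' (the Monte Carlo estimate of the true intensity from many partial still
#' observations).
#'
#' @param obs `data.frame` with integer columns `h`, `k`, `l` and an
#'   intensity column `I`.
#' @param laue_group Only `"4/mmm"`.
#' @return `data.frame` with canonical `h`, `k`, `l`, `I_merged`, `n_obs`.
#' @export
mc_merge <- function(obs, laue_group = "4/mmm") {
  stopifnot(all(c("h", "k", "l", "I") %in% names(obs)))
  if (!nrow(obs)) {
    return(data.frame(h = integer(0), k = integer(0), l = integer(0),
                      I_merged = numeric(0), n_obs = integer(0)))
  }
  canon <- canonical_hkl(as.matrix(obs[, c("h", "k", "l")]), laue_group)
  key <- .hkl_key(canon[, 1], canon[, 2], canon[, 3])
  f <- factor(key, levels = unique(key))
  I_merged <- as.numeric(tapply(obs$I, f, mean))
  n_obs <- as.integer(tapply(obs$I, f, length))
  first <- !duplicated(key)
  data.frame(h = canon[first, 1], k = canon[first, 2], l = canon[first, 3],
             I_merged = I_merged, n_obs = n_obs)
}

#' Split observations into two random half-sets
#'
#' Observations of each unique reflection are randomly permuted (seeded)
#' and assigned alternately to the two halves, so every reflection with at
#' least 2 observations appears in both halves (a 2/2 or 3/2 split etc.).
#' Reflections with a single observation are excluded and counted.
#'
#' @param obs Observation table as in [mc_merge()].
#' @param seed Integer seed; the same seed reproduces the same split.
#' @param laue_group Only `"4/mmm"`.
#' @return List with observation tables `a` and `b` (with canonical
#'   indices) and `n_excluded`, the number of single-observation
#'   reflections dropped.
#' @export
split_half <- function(obs, seed = 1L, laue_group = "4/mmm") {
  stopifnot(all(c("h", "k", "l", "I") %in% names(obs)), nrow(obs) > 0)
  canon <- canonical_hkl(as.matrix(obs[, c("h", "k", "l")]), laue_group)
  key <- .hkl_key(canon[, 1], canon[, 2], canon[, 3])
  obs2 <- data.frame(h = canon[, 1], k = canon[, 2], l = canon[, 3], I = obs$I)
  groups <- split(seq_len(nrow(obs2)), key)
  singletons <- vapply(groups, length, integer(1)) < 2L
  n_excluded <- sum(singletons)
  if (n_excluded) {
    message(n_excluded, " reflection(s) with < 2 observations excluded from the split")
  }
  groups <- groups[!singletons]
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  ia <- integer(0); ib <- integer(0)
  for (g in groups) {
    p <- if (length(g) > 1L) sample(g) else g
    odd <- seq_along(p) %% 2L == 1L
    ia <- c(ia, p[odd])
    ib <- c(ib, p[!odd])
  }
  list(a = obs2[ia, , drop = FALSE], b = obs2[ib, , drop = FALSE],
       n_excluded = n_excluded)
}

# join two merged tables on their common canonical HKL set
.join_halves <- function(a, b) {
  ka <- .hkl_key(a$h, a$k, a$l)
  kb <- .hkl_key(b$h, b$k, b$l)
  common <- intersect(ka, kb)
  if (!length(common)) stop("halves share no reflections")
  list(ia = a$I_merged[match(common, ka)], ib = b$I_merged[match(common, kb)])
}

#' Half-set disagreement statistic R_split
#'
#' `R_split = 100 / sqrt(2) * sum |I_A - I_B| / (0.5 * sum (I_A + I_B))`
#' over the common reflection set of the two merged halves; lower is
#' better. Undefined (error) when the denominator is not positive.
#'
#' @param merged_a,merged_b Merged tables from [mc_merge()] (columns `h`,
#'   `k`, `l`, `I_merged`).
#' @return R_split in percent.
#' @export
r_split <- function(merged_a, merged_b) {
  j <- .join_halves(merged_a, merged_b)
  den <- 0.5 * sum(j$ia + j$ib)
  if (!is.finite(den) || den <= 0) stop("R_split undefined: non-positive denominator")
  100 / sqrt(2) * sum(abs(j$ia - j$ib)) / den
}

#' Half-set correlation CC1/2
#'
#' Pearson correlation (in percent) between the merged intensities of two
#' half-data sets on their common reflection set.
#'
#' @inheritParams r_split
#' @return CC1/2 in percent.
#' @export
cc_half <- function(merged_a, merged_b) {
  j <- .join_halves(merged_a, merged_b)
  if (length(j$ia) < 3L) stop("CC1/2 undefined: need >= 3 common reflections")
  if (stats::sd(j$ia) == 0 || stats::sd(j$ib) == 0) {
    stop("CC1/2 undefined: degenerate (zero-variance) half")
  }
  100 * stats::cor(j$ia, j$ib)
}

#' Completeness of an observed reflection set
#'
#' 100 times the number of distinct observed unique reflections inside the
#' resolution range divided by the theoretical count from
#' [count_unique()] with the same conventions.
#'
#' @param observed `data.frame` with columns `h`, `k`, `l` (any
#'   symmetry-equivalent indexing).
#' @param cell,laue_group,d_max,d_min,include_absences As in
#'   [count_unique()].
#' @return Completeness in percent.
#' @export
completeness <- function(observed, cell, laue_group = "4/mmm", d_max, d_min,
                         include_absences = FALSE) {
  theo <- count_unique(cell, laue_group, d_max, d_min, include_absences)
  if (theo == 0L) stop("no theoretical reflections in this range")
  if (!nrow(observed)) return(0)
  canon <- canonical_hkl(as.matrix(observed[, c("h", "k", "l")]), laue_group)
  d <- .d_tetragonal(canon[, 1], canon[, 2], canon[, 3], cell[1], cell[3])
  keep <- d >= d_min & d <= d_max
  if (!include_absences) keep <- keep & !.is_absent_p43212(canon[, 1], canon[, 2], canon[, 3])
  n_obs <- sum(!duplicated(.hkl_key(canon[, 1], canon[, 2], canon[, 3])[keep] ))
  100 * n_obs / theo
}

#' Read / write reflection observations as plain text
#'
#' One row per observation: columns `h k l I sigma` (whitespace separated,
#' header optional on read, written with a header).
#'
#' @param path File path.
#' @return `read_observations` returns a `data.frame` with columns `h`,
#'   `k`, `l`, `I`, `sigma`.
#' @export
read_observations <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("[A-Za-z]", first)
  df <- utils::read.table(path, header = header)
  names(df) <- c("h", "k", "l", "I", "sigma")[seq_len(ncol(df))]
  df
}

#' @rdname read_observations
#' @param obs Observation table (columns `h`, `k`, `l`, `I`, optionally
#'   `sigma`).
#' @export
write_observations <- function(obs, path) {
  cols <- intersect(c("h", "k", "l", "I", "sigma"), names(obs))
  utils::write.table(obs[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
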