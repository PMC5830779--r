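# Bullet enumeration, application, attractor classification and the
# threshold-based therapeutic verdict.
#
# A bullet is a couple (targets, modalities): a combination without
# repetition of r node names and an arrangement with repetition of r domain
# levels, aligned index-wise. Applying a bullet to the pathological variant
# yields the testing variant; a bullet is therapeutic when it raises the
# physiological part of the state space from x% (pathological) to y%
# (testing) with y - x >= delta, without creating de novo attractors.

#' Construct a bullet
#'
#' @param targets Character vector of r distinct node names.
#' @param modalities Numeric vector of r domain levels; `modalities[i]` is
#'   forced on `targets[i]` (0 = inhibition, 1 = activation, intermediate
#'   levels under multivalued logic).
#' @return An object of class `bullet`.
#' @export
bullet <- function(targets, modalities) {
  if (length(targets) != length(modalities) || length(targets) < 1L)
    stop("a bullet needs r >= 1 targets with one modality each", call. = FALSE)
  if (anyDuplicated(targets))
    stop("bullet targets must be distinct", call. = FALSE)
  structure(list(targets = as.character(targets), modalities = as.numeric(modalities)),
            class = "bullet")
}

#' Format a bullet as `target[level]` tokens
#' @param x A `bullet`.
#' @return String such as `"do[0] factory[1]"`.
#' @export
format_bullet <- function(x) {
  paste(sprintf("%s[%s]", x$targets, format_level(x$modalities)), collapse = " ")
}

#' Parse `target[level]` tokens back into a bullet
#' @param text String of whitespace-separated `target[level]` tokens.
#' @return A `bullet`.
#' @export
parse_bullet <- function(text) {
  toks <- strsplit(trimws(text), "[ \t]+")[[1]]
  m <- regmatches(toks, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\[([0-9.]+)\\]$", toks))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stop(sprintf("invalid bullet token(s): %s", paste(toks[bad], collapse = " ")),
         call. = FALSE)
  bullet(vapply(m, `[`, character(1), 2L), as.numeric(vapply(m, `[`, character(1), 3L)))
}

#' @export
print.bullet <- function(x, ...) {
  cat("<bullet>", format_bullet(x), "\n")
  invisible(x)
}

#' Number of possible bullets
#'
#' With r targets per bullet among n nodes and h logic levels there are
#' `C(n, r) * h^r` possible bullets (target combinations times modality
#' arrangements).
#'
#' @param n Number of nodes.
#' @param r Targets per bullet.
#' @param h Number of logic levels.
#' @return Numeric count.
#' @examples
#' count_bullets(9, 2, 2) # 144
#' @export
count_bullets <- function(n, r, h) {
  if (r < 1 || r > n) stop("'r' must satisfy 1 <= r <= n", call. = FALSE)
  if (h < 2) stop("'h' must be >= 2", call. = FALSE)
  choose(n, r) * h^r
}

#' Enumerate (or sample) the bullets of a model
#'
#' Exhaustive enumeration is deterministic and lexicographic: target
#' combinations in node order, modality arrangements with the last target
#' varying fastest. When `maxtarg`/`maxmoda` cap the totals, combinations
#' and arrangements are sampled uniformly without replacement (uses R's RNG).
#' Every node is eligible as a target, including inputs and pathologically
#' forced nodes; `exclude` removes nodes on request.
#'
#' @param model A `logical_model` (or `variant`, whose base model is used).
#' @param n_targ Targets per bullet (r).
#' @param maxtarg Cap on target combinations tested.
#' @param maxmoda Cap on modality arrangements per combination.
#' @param exclude Optional node names never used as targets.
#' @return List of `bullet` objects.
#' @export
enumerate_bullets <- function(model, n_targ = 1L, maxtarg = Inf, maxmoda = Inf,
                              exclude = character(0)) {
  v <- as_variant(model)
  nodes <- setdiff(v$model$nodes, exclude)
  h <- v$model$domain$h
  r <- as.integer(n_targ)
  if (r < 1 || r > length(nodes))
    stop("'n_targ' must satisfy 1 <= n_targ <= number of eligible nodes",
         call. = FALSE)
  combos <- utils::combn(nodes, r, simplify = FALSE)
  if (maxtarg < length(combos))
    combos <- combos[sort(sample.int(length(combos), maxtarg))]
  levels <- (0:(h - 1L)) / (h - 1L)
  grid <- expand.grid(rev(replicate(r, levels, simplify = FALSE)),
                      KEEP.OUT.ATTRS = FALSE)
  arrangements <- lapply(seq_len(nrow(grid)), function(i)
    rev(as.numeric(grid[i, ])))
  out <- list()
  for (cb in combos) {
    arr <- arrangements
    if (maxmoda < length(arr)) arr <- arr[sort(sample.int(length(arr), maxmoda))]
    for (md in arr) out[[length(out) + 1L]] <- bullet(cb, md)
  }
  out
}

#' Apply a bullet to the pathological variant
#'
#' Returns the testing variant: pathological forcings plus bullet forcings,
#' the bullet overriding on collision (so reversal bullets, which undo a
#' pathological forcing, are testable).
#'
#' @param patho A `variant` (typically pathological).
#' @param b A `bullet`.
#' @return A `variant` labelled `"testing"`.
#' @export
apply_bullet <- function(patho, b) {
  apply_forcings(as_variant(patho), stats::setNames(b$modalities, b$targets),
                 label = "testing")
}

#' Classify a test attractor against the physiological and pathological sets
#'
#' Matching is exact full-state equality of canonical state sets (no partial
#' matching): `"physiological"` when the attractor equals a member of
#' `a_physio`, else `"pathological"` when it equals a member of `a_patho`,
#' else `"de_novo"`.
#'
#' @param att An `attractor`.
#' @param a_physio,a_patho `attractor_set`s computed on the same model and
#'   node order.
#' @return One of `"physiological"`, `"pathological"`, `"de_novo"`, with the
#'   matched attractor's label as attribute `"match"` (when matched).
#' @export
classify_attractor <- function(att, a_physio, a_patho) {
  if (!identical(a_physio$nodes, a_patho$nodes) ||
      !identical(colnames(att$states), a_physio$nodes))
    stop("attractor sets were not computed on the same node order", call. = FALSE)
  keys_physio <- vapply(a_physio$attractors, `[[`, character(1), "key")
  keys_patho <- vapply(a_patho$attractors, `[[`, character(1), "key")
  i <- match(att$key, keys_physio)
  if (!is.na(i))
    return(structure("physiological", match = a_physio$attractors[[i]]$label))
  i <- match(att$key, keys_patho)
  if (!is.na(i))
    return(structure("pathological", match = a_patho$attractors[[i]]$label))
  "de_novo"
}

# Physiological part of a state space: sum of the basin percentages of the
# attractors of `aset` whose canonical state set equals a physiological one.
physiological_part <- function(aset, a_physio, a_patho) {
  pct <- basin_percentages(aset)
  cls <- vapply(aset$attractors, function(a)
    as.character(classify_attractor(a, a_physio, a_patho)), character(1))
  sum(pct[cls == "physiological"])
}

#' Assess one bullet
#'
#' Computes the testing attractor set, classifies every attractor against the
#' physiological and pathological references, and derives the gain
#' `x% -> y%`, where x is the physiological part of the pathological state
#' space (computed once per screen from `a_patho`) and y the physiological
#' part of the testing state space. Therapeutic iff `y - x >= delta` and no
#' de novo attractor appeared. The comparison uses unrounded percentages.
#'
#' @param patho Pathological `variant`.
#' @param b A `bullet`.
#' @param a_physio,a_patho Reference `attractor_set`s (computed once per
#'   screen).
#' @param config A [search_config()] for the testing run.
#' @param delta Gain threshold in percentage points (default 5).
#' @return An object of class `assessment`: `bullet`, `x`, `y`, `gain`,
#'   `basins` (percentage of the testing space per matched reference
#'   attractor label), `de_novo_count`, `therapeutic`, `test_set`.
#' @export
assess_bullet <- function(patho, b, a_physio, a_patho,
                          config = search_config(), delta = 5) {
  x <- physiological_part(a_patho, a_physio, a_patho)
  test_var <- apply_bullet(patho, b)
  a_test <- find_attractors(test_var, config)
  pct <- unname(basin_percentages(a_test))
  labels_physio <- vapply(a_physio$attractors, `[[`, character(1), "label")
  labels_patho <- vapply(a_patho$attractors, `[[`, character(1), "label")
  basins <- stats::setNames(
    numeric(length(labels_physio) + length(labels_patho)),
    c(paste0("physio:", labels_physio), paste0("patho:", labels_patho)))
  de_novo <- 0L
  y <- 0
  for (i in seq_along(a_test$attractors)) {
    cls <- classify_attractor(a_test$attractors[[i]], a_physio, a_patho)
    if (cls == "de_novo") {
      de_novo <- de_novo + 1L
      basins[paste0("denovo:", a_test$attractors[[i]]$label)] <- pct[i]
    } else {
      prefix <- if (cls == "physiological") "physio:" else "patho:"
      basins[paste0(prefix, attr(cls, "match"))] <- pct[i]
      if (cls == "physiological") y <- y + pct[i]
    }
  }
  structure(list(bullet = b, x = x, y = y, gain = y - x, basins = basins,
                 de_novo_count = de_novo,
                 therapeutic = (de_novo == 0L) && (y - x >= delta),
                 unresolved = a_test$unresolved, test_set = a_test),
            class = "assessment")
}

#' @export
print.assessment <- function(x, ...) {
  cat(sprintf("<assessment> %s: %.1f%% -> %.1f%% (gain %.1f)%s%s\n",
              format_bullet(x$bullet), x$x, x$y, x$gain,
              if (x$therapeutic) " therapeutic" else "",
              if (x$de_novo_count) sprintf(" [%d de novo]", x$de_novo_count) else ""))
  invisible(x)
}

#' Screen all bullets of a given size for therapeutic potential
#'
#' Computes the physiological and pathological attractor sets once, then
#' assesses every bullet (or a sampled subset under `maxtarg`/`maxmoda`).
#' Each bullet's testing run uses a seed derived deterministically from the
#' global seed and the bullet itself, so adding or removing bullets from the
#' test set does not perturb the randomness of the others.
#'
#' @param physio Physiological `variant` (or `logical_model`).
#' @param patho Pathological `variant`.
#' @param n_targ Targets per bullet (r).
#' @param delta Gain threshold in percentage points.
#' @param config A [search_config()]; its `seed` is the global screen seed.
#' @param maxtarg,maxmoda Sampling caps, see [enumerate_bullets()].
#' @param exclude Node names never used as targets.
#' @param a_physio,a_patho Optional precomputed reference attractor sets
#'   (so several screens can share one pair of reference runs).
#' @return An object of class `screen_result`: `therapeutic` (assessments
#'   sorted by decreasing gain, ties by bullet token), `log` (all tested
#'   bullets), `x`, `delta`, `a_physio`, `a_patho`, `n_tested`.
#' @export
screen <- function(physio, patho, n_targ = 1L, delta = 5,
                   config = search_config(), maxtarg = Inf, maxmoda = Inf,
                   exclude = character(0), a_physio = NULL, a_patho = NULL) {
  physio <- as_variant(physio)
  patho <- as_variant(patho)
  seed <- config$seed
  if (is.null(a_physio)) {
    cfg <- config; cfg$seed <- derive_seed(seed, "physio")
    a_physio <- find_attractors(physio, cfg)
  }
  if (is.null(a_patho)) {
    cfg <- config; cfg$seed <- derive_seed(seed, "patho")
    a_patho <- find_attractors(patho, cfg)
  }
  if (!is.null(seed)) set.seed(derive_seed(seed, "bullets"))
  bullets <- enumerate_bullets(patho, n_targ = n_targ, maxtarg = maxtarg,
                               maxmoda = maxmoda, exclude = exclude)
  log <- vector("list", length(bullets))
  for (i in seq_along(bullets)) {
    cfg <- config
    cfg$seed <- derive_seed(seed, format_bullet(bullets[[i]]))
    log[[i]] <- assess_bullet(patho, bullets[[i]], a_physio, a_patho,
                              config = cfg, delta = delta)
  }
  ther <- Filter(function(a) a$therapeutic, log)
  if (length(ther)) {
    gains <- vapply(ther, `[[`, numeric(1), "gain")
    toks <- vapply(ther, function(a) format_bullet(a$bullet), character(1))
    ther <- ther[order(-gains, toks)]
  }
  structure(list(therapeutic = ther, log = log,
                 x = physiological_part(a_patho, a_physio, a_patho),
                 delta = delta, a_physio = a_physio, a_patho = a_patho,
                 n_tested = length(bullets)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d bullet(s) tested, %d therapeutic (delta = %s, x = %.1f%%)\n",
              x$n_tested, length(x$therapeutic), format(x$delta), x$x))
  for (a in x$therapeutic)
    cat(sprintf("  %s  %.1f%% -> %.1f%%\n", format_bullet(a$bullet), a$x, a$y))
  invisible(x)
}

# Deterministic per-stream seed derivation: a small polynomial string hash
# folded with the global seed, kept inside the 32-bit integer range R
# requires of set.seed(). NULL stays NULL (inherit the current RNG state).
derive_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  m <- 2147483647
  acc <- as.numeric(seed) %% m
  for (code in utf8ToInt(tag)) acc <- (acc * 131 + code) %% m
  as.integer(acc)
}
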