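.chemotaxmap <- new.env(parent = emptyenv())

preset_file <- function() {
  system.file("extdata", "table1.yaml", package = "chemotaxmap",
              mustWork = TRUE)
}

load_presets <- function() {
  if (is.null(.chemotaxmap$presets)) {
    raw <- yaml::read_yaml(preset_file())
    .chemotaxmap$presets <- lapply(raw$presets, parse_preset)
    for (nm in names(.chemotaxmap$presets))
      .chemotaxmap$presets[[nm]]$name <- nm
    .chemotaxmap$stated <- unlist(raw$stated_patterns)
  }
  .chemotaxmap$presets
}

parse_preset <- function(p) {
  list(pA = species_params(p$A$D, p$A$k, p$A$c, p$A$alpha),
       pI = species_params(p$I$D, p$I$k, p$I$c, p$I$alpha),
       L = p$L,
       G_star = if (is.null(p$G_star)) NA_real_ else p$G_star,
       g = if (is.null(p$g)) NA_real_ else p$g)
}

alias_for_pattern <- c(BI_REPEL_TO_ATTRACT = "repulsion_to_attraction",
                       UNI_REPEL = "uni_repulsion",
                       UNI_ATTRACT = "uni_attraction",
                       BAR = "bar")

# Pattern aliases bound by computed classification, not by column labels:
# each response-curve column is classified at load time and an alias name
# points at the first column (in printed order) realising that pattern.
preset_aliases <- function() {
  if (is.null(.chemotaxmap$aliases)) {
    pres <- load_presets()
    cols <- grep("^fig3", names(pres), value = TRUE)
    pat <- vapply(cols, function(nm)
      classify_response(pres[[nm]]$pA, pres[[nm]]$pI, pres[[nm]]$L),
      character(1))
    al <- character(0)
    for (i in seq_along(cols)) {
      a <- alias_for_pattern[[pat[i]]]
      if (!a %in% names(al)) al[a] <- cols[i]
    }
    .chemotaxmap$aliases <- al
    .chemotaxmap$computed_patterns <- pat
  }
  .chemotaxmap$aliases
}

#' Built-in reference parameter presets
#'
#' Six canonical activator/inhibitor parameter columns ship with the
#' package: two profile presets with their stimulus (`"fig2C"` attraction,
#' `"fig2D"` its A/I-swapped repulsion twin) and four response-curve
#' presets (`"fig3B"` to `"fig3E"`) covering the concentration-dependent
#' patterns. The response-curve presets are additionally reachable under
#' pattern-name aliases (`"bar"`, `"repulsion_to_attraction"`,
#' `"uni_attraction"`, `"uni_repulsion"`) that are bound by *computed*
#' classification at load time - see [preset_classification()] for the
#' self-check, including the columns whose computed pattern disagrees with
#' their traditional label.
#'
#' @param name Preset key or pattern alias.
#' @return `table1_preset`: list with `pA`, `pI`, `L`, and (profile
#'   presets only) `G_star`, `g`. `preset_names`: character vector of valid
#'   keys. `preset_classification`: data frame with the per-column stated
#'   and computed patterns.
#' @examples
#' table1_preset("fig3E")$pA
#' preset_classification()
#' @export
table1_preset <- function(name) {
  pres <- load_presets()
  al <- preset_aliases()
  if (name %in% names(al)) name <- al[[name]]
  if (!name %in% names(pres)) {
    extra <- ""
    if (name %in% unname(alias_for_pattern)) {
      pat <- names(alias_for_pattern)[match(name, alias_for_pattern)]
      extra <- sprintf(
        "; no shipped column classifies as %s (see preset_classification())",
        pat)
    }
    stop(sprintf("unknown preset '%s'; available: %s%s", name,
                 paste(c(names(pres), names(al)), collapse = ", "), extra),
         call. = FALSE)
  }
  pres[[name]]
}

#' @rdname table1_preset
#' @export
preset_names <- function() {
  c(names(load_presets()), names(preset_aliases()))
}

#' @rdname table1_preset
#' @export
preset_classification <- function() {
  pres <- load_presets()
  preset_aliases()
  cols <- grep("^fig3", names(pres), value = TRUE)
  data.frame(preset = cols,
             stated = unname(.chemotaxmap$stated[cols]),
             computed = unname(.chemotaxmap$computed_patterns[cols]),
             agrees = unname(.chemotaxmap$stated[cols] ==
                               .chemotaxmap$computed_patterns[cols]),
             row.names = NULL)
}

#' Serialise and reload a preset
#'
#' Round-trippable YAML serialisation of a preset (the packaged config
#' format): `write_preset()` then `read_preset()` reproduces the preset
#' exactly.
#'
#' @param preset A preset as returned by [table1_preset()].
#' @param path File path.
#' @return `read_preset` returns the preset list.
#' @export
write_preset <- function(preset, path) {
  out <- list(A = preset$pA[c("D", "k", "c", "alpha")],
              I = preset$pI[c("D", "k", "c", "alpha")],
              L = preset$L)
  if (is.finite(preset$G_star)) out$G_star <- preset$G_star
  if (is.finite(preset$g)) out$g <- preset$g
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @rdname write_preset
#' @export
read_preset <- function(path) {
  parse_preset(yaml::read_yaml(path))
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

default_sample_ranges <- function() {
  list(D = c(0.5, 100), k = c(0.5, 50), c = c(0.01, 300), alpha = c(0.1, 20))
}

#' Random activator/inhibitor parameter draws
#'
#' Log-uniform samples of the eight kinetic constants, reproducible per
#' seed, each tagged with its BAR-condition outcome and computed pattern.
#' The default ranges cover the reference presets' order-of-magnitude
#' spread and realise all four response patterns in a couple of hundred
#' draws.
#'
#' @param ranges Named list of `c(min, max)` ranges for `D`, `k`, `c`,
#'   `alpha` (applied to both species). Ranges may collapse to a point.
#' @param n Number of draws.
#' @param seed Integer seed; the global RNG state is left untouched.
#' @param L Growth-cone length used for tagging.
#' @return List of draws, each a list with `pA`, `pI`, `bar_satisfied`,
#'   `pattern`.
#' @examples
#' draws <- sample_parameters(n = 5, seed = 1)
#' vapply(draws, `[[`, character(1), "pattern")
#' @export
sample_parameters <- function(ranges = default_sample_ranges(), n, seed,
                              L = 10) {
  stopifnot(n >= 1)
  need <- c("D", "k", "c", "alpha")
  if (!all(need %in% names(ranges)))
    stop("ranges must name D, k, c and alpha", call. = FALSE)
  for (r in ranges[need])
    if (length(r) != 2L || any(r <= 0) || r[1] > r[2])
      stop("each range must be a positive non-decreasing pair", call. = FALSE)
  runif_log <- function(m, r) exp(stats::runif(m, log(r[1]), log(r[2])))
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      draw <- function() species_params(D = runif_log(1, ranges$D),
                                        k = runif_log(1, ranges$k),
                                        c = runif_log(1, ranges$c),
                                        alpha = runif_log(1, ranges$alpha))
      pA <- draw(); pI <- draw()
      list(pA = pA, pI = pI,
           bar_satisfied = bar_condition(pA, pI, L)$satisfied,
           pattern = classify_response(pA, pI, L))
    })
  })
}
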