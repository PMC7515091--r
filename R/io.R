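#' Read and write reaction-network model files
#'
#' Model files are JSON or YAML with the layout
#' \preformatted{
#' {"species": ["X"], "x0": [0],
#'  "reactions": [
#'    {"name": "birth", "reactants": {}, "products": {"X": 1}, "rate": 1.0},
#'    {"name": "death", "reactants": {"X": 1}, "products": {}, "rate": 0.1}]}
#' }
#' Reactant/product maps give integer stoichiometries keyed by species
#' name; only mass-action kinetics are expressible in files.  The schema
#' is validated strictly, with errors naming the offending reaction and
#' field.  Writing then reading a model round-trips to the same system.
#'
#' @param path file path; the format is chosen by extension (`.json`, or
#'   `.yaml`/`.yml`) unless `format` is given.
#' @param format `"json"` or `"yaml"`.
#' @return `readReactionSystem()`: list with `system` and `x0`.
#' @export
readReactionSystem <- function(path, format = NULL) {
  format <- format %||% .guessFormat(path)
  raw <- if (format == "json") jsonlite::fromJSON(path, simplifyVector = FALSE)
    else yaml::yaml.load_file(path)
  .parseModel(raw, path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.guessFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, json = "json", yaml = , yml = "yaml",
    stop("cannot infer model format from extension: ", path))
}

.parseModel <- function(raw, path) {
  fail <- function(...) stop("model file ", path, ": ", ..., call. = FALSE)
  for (f in c("species", "x0", "reactions"))
    if (is.null(raw[[f]])) fail("missing top-level field '", f, "'")
  species <- as.character(unlist(raw$species))
  if (!length(species) || anyDuplicated(species))
    fail("'species' must be a non-empty list of unique names")
  x0 <- unlist(raw$x0)
  if (length(x0) != length(species) || any(x0 < 0) || any(x0 != round(x0)))
    fail("'x0' must give one non-negative integer per species")
  if (!length(raw$reactions)) fail("'reactions' must be non-empty")
  nr <- length(raw$reactions)
  ns <- length(species)
  react <- prod <- matrix(0L, nr, ns)
  rates <- numeric(nr)
  nms <- character(nr)
  for (i in seq_len(nr)) {
    rx <- raw$reactions[[i]]
    where <- sprintf("reaction %d", i)
    for (f in c("name", "rate"))
      if (is.null(rx[[f]])) fail(where, ": missing field '", f, "'")
    nms[i] <- as.character(rx$name)
    rate <- rx$rate
    if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
      fail(where, " ('", nms[i], "'): 'rate' must be a positive number")
    rates[i] <- rate
    react[i, ] <- .parseSide(rx$reactants, species,
      sprintf("%s ('%s') reactants", where, nms[i]), fail)
    prod[i, ] <- .parseSide(rx$products, species,
      sprintf("%s ('%s') products", where, nms[i]), fail)
  }
  list(system = ReactionSystem(species, react, prod, rates, nms),
    x0 = as.integer(x0))
}

.parseSide <- function(side, species, where, fail) {
  out <- integer(length(species))
  if (is.null(side) || !length(side)) return(out)
  if (is.null(names(side)) || any(names(side) == ""))
    fail(where, ": stoichiometries must be keyed by species name")
  unknown <- setdiff(names(side), species)
  if (length(unknown))
    fail(where, ": unknown species '", unknown[1L], "'")
  v <- unlist(side)
  if (any(v < 0) || any(v != round(v)))
    fail(where, ": stoichiometries must be non-negative integers")
  out[match(names(side), species)] <- as.integer(v)
  out
}

#' @rdname readReactionSystem
#' @param system a [ReactionSystem-class].
#' @param x0 initial population state.
#' @return `writeReactionSystem()`: the path, invisibly.
#' @export
writeReactionSystem <- function(system, x0, path, format = NULL) {
  format <- format %||% .guessFormat(path)
  x0 <- .checkSpeciesState(system, x0, "x0")
  side <- function(v) {
    i <- which(v > 0L)
    if (!length(i)) return(structure(list(), names = character(0)))
    as.list(stats::setNames(as.integer(v[i]), system@speciesNames[i]))
  }
  obj <- list(
    species = as.list(system@speciesNames),
    x0 = as.list(as.integer(x0)),
    reactions = lapply(seq_len(numReactions(system)), function(n) list(
      name = system@reactionNames[n],
      reactants = side(system@reactantStoich[n, ]),
      products = side(system@productStoich[n, ]),
      rate = system@rateConstants[n])))
  if (format == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' Write a distribution as TSV with a provenance header
#'
#' Commented `# key=value` metadata lines (truncation depth, tolerance,
#' per-time tail mass) followed by columns `time`, `state`,
#' `probability`.
#'
#' @param dist a [ReactionDistribution-class] or
#'   [SpeciesDistribution-class].
#' @param file path or connection.
#' @return The data.frame, invisibly.
#' @export
writeDistribution <- function(dist, file = stdout()) {
  if (is(dist, "ReactionDistribution")) {
    states <- .stateKeys(dist@generator@space@states)
    meta <- c(sprintf("# M=%d", dist@generator@space@M),
      sprintf("# eps=%g", dist@eps),
      sprintf("# tail_mass=%s", paste(signif(dist@tailMass, 8),
        collapse = ",")))
  } else {
    states <- .stateKeys(dist@states)
    meta <- sprintf("# truncation_error=%g", dist@truncationError)
  }
  df <- data.frame(
    time = rep(dist@times, each = length(states)),
    state = rep(states, length(dist@times)),
    probability = as.vector(dist@probs))
  if (is.character(file)) {
    con <- file(file, "w")
    on.exit(close(con))
  } else con <- file
  writeLines(meta, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
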