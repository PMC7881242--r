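#' Biogeographic grouping of zooplankton taxa
#'
#' A grouping scheme is a named character vector mapping taxon name to
#' biogeographic group name. [defaultGroupingScheme()] returns the standard
#' Irish Sea assignment of 14 taxa to five groups; group names are
#' normalized through [canonicalGroupName()], which resolves the synonyms
#' that circulate in the literature (e.g. "Cold Temperate" for the
#' Temperate Oceanic group).
#'
#' @return Named character vector, `names` = taxa, values = canonical group
#'   names.
#' @export
#' @examples
#' defaultGroupingScheme()["Calanus helgolandicus"]
defaultGroupingScheme <- function() {
  c("Cyphonautes larvae"        = "Warm Temperate",
    "Calanus helgolandicus"     = "Warm Temperate Oceanic",
    "Decapod larvae"            = "Warm Temperate Oceanic",
    "Cirripede larvae"          = "Warm Temperate Oceanic",
    "Euphausiids"               = "Warm Temperate Oceanic",
    "Acartia spp."              = "Temperate Oceanic",
    "Podon spp."                = "Temperate Oceanic",
    "Evadne spp."               = "Temperate Oceanic",
    "Pseudocalanus"             = "Shelf Sea",
    "Para-Pseudocalanus spp."   = "Shelf Sea",
    "Temora longicornis"        = "Shelf Sea",
    "Fish larvae"               = "Shelf Sea",
    "Calanus finmarchicus"      = "Sub Arctic",
    "Tomopteris spp."           = "Sub Arctic")
}

#' Canonical biogeographic group names
#'
#' @return Character vector of the five canonical group names.
#' @export
canonicalGroups <- function() {
  c("Warm Temperate", "Warm Temperate Oceanic", "Temperate Oceanic",
    "Shelf Sea", "Sub Arctic")
}

# Built-in synonym map; users may extend via the `aliases` arguments.
.defaultAliases <- function() {
  c("Cold Temperate"          = "Temperate Oceanic",
    "Cold Temperate Oceanic"  = "Warm Temperate Oceanic",
    "Cold temperate plankton" = "Temperate Oceanic",
    "Warm Temperatecean"      = "Warm Temperate Oceanic",
    "Warm Temperate Ocean"    = "Warm Temperate Oceanic",
    "Sub Artic"               = "Sub Arctic",
    "Sub-Arctic"              = "Sub Arctic")
}

#' Normalize a group name to its canonical form
#'
#' @param name character vector of group names (canonical names pass
#'   through unchanged).
#' @param aliases optional named character vector of extra synonym -> canonical
#'   entries, merged over the built-in map.
#' @return Character vector of canonical names; unknown names are returned
#'   unchanged.
#' @export
#' @examples
#' canonicalGroupName("Cold Temperate")
canonicalGroupName <- function(name, aliases = NULL) {
  map <- .defaultAliases()
  if (!is.null(aliases)) map[names(aliases)] <- aliases
  hit <- match(name, names(map))
  out <- name
  out[!is.na(hit)] <- map[hit[!is.na(hit)]]
  out
}

#' Sum taxon columns into biogeographic group columns
#'
#' Taxa named in `scheme` are summed into their group column; environmental
#' variables pass through unchanged; taxa present in the table but absent
#' from the scheme (no strong biogeographic affinity) are dropped with a
#' warning.
#'
#' @param x a [SampleTable-class].
#' @param scheme named character vector, taxon -> group (see
#'   [defaultGroupingScheme()]).
#' @param aliases optional extra group-name synonyms for
#'   [canonicalGroupName()].
#' @return A [SampleTable-class] whose abundance columns are groups
#'   (varType `"group"`).
#' @export
applyGrouping <- function(x, scheme = defaultGroupingScheme(),
                          aliases = NULL) {
  stopifnot(is(x, "SampleTable"))
  if (!length(scheme)) stop("empty grouping scheme")
  if (anyDuplicated(names(scheme)))
    stop("taxon mapped to two groups: ",
         paste(unique(names(scheme)[duplicated(names(scheme))]),
               collapse = ", "))
  scheme <- setNames(canonicalGroupName(scheme, aliases), names(scheme))
  vt <- variableTypes(x)
  taxa <- names(vt)[vt != "env"]
  envs <- names(vt)[vt == "env"]
  mapped <- intersect(taxa, names(scheme))
  if (!length(mapped))
    stop("grouping scheme maps none of the table's taxa")
  dropped <- setdiff(taxa, mapped)
  if (length(dropped))
    warning("dropping ", length(dropped), " ungrouped taxa: ",
            paste(dropped, collapse = ", "))
  groups <- unique(scheme[mapped])
  gv <- vapply(groups, function(g) {
    member <- mapped[scheme[mapped] == g]
    rowSums(sampleValues(x)[, member, drop = FALSE])
  }, numeric(nrow(x)))
  gv <- matrix(gv, nrow = nrow(x),
               dimnames = list(rownames(sampleValues(x)), groups))
  vals <- cbind(gv, sampleValues(x)[, envs, drop = FALSE])
  SampleTable(vals, date = if (length(x@date)) x@date,
              lon = if (length(x@lon)) x@lon,
              lat = if (length(x@lat)) x@lat,
              varType = setNames(c(rep("group", length(groups)),
                                   rep("env", length(envs))),
                                 c(groups, envs)))
}
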