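#' Land-cover classification scheme
#'
#' Maps a detailed source nomenclature (e.g. a CORINE-style 44-class
#' inventory) onto the ~10 dominant land-cover types (DLCT) on which all
#' accounts run, and attaches a greenness weight in \[0, 1\] to every DLCT
#' (used by the landscape-potential account).
#'
#' @param source_classes data.frame with columns `code`, `name`.
#' @param dlct_classes data.frame with columns `code`, `name`.
#' @param mapping Named integer vector: names are source codes (as
#'   character), values are DLCT codes. Must be total over `source_classes`.
#' @param green_weight Named numeric vector in \[0,1\], one entry per DLCT
#'   code.
#' @return Object of class `classification_scheme`.
#' @export
classification_scheme <- function(source_classes, dlct_classes, mapping,
                                  green_weight) {
  mapping <- vapply(mapping, as.integer, integer(1))
  miss <- setdiff(as.character(source_classes$code), names(mapping))
  if (length(miss))
    stop_encar("mapping is not total: source codes without a DLCT: %s",
               paste(miss, collapse = ", "))
  bad <- setdiff(unique(mapping), dlct_classes$code)
  if (length(bad))
    stop_encar("mapping targets unknown DLCT codes: %s",
               paste(bad, collapse = ", "))
  gw_miss <- setdiff(as.character(dlct_classes$code), names(green_weight))
  if (length(gw_miss))
    stop_encar("green_weight missing for DLCT codes: %s",
               paste(gw_miss, collapse = ", "))
  if (any(green_weight < 0 | green_weight > 1))
    stop_encar("green weights must lie in [0, 1]")
  structure(list(source_classes = source_classes,
                 dlct_classes = dlct_classes,
                 mapping = mapping, green_weight = green_weight),
            class = "classification_scheme")
}

#' @export
print.classification_scheme <- function(x, ...) {
  cat(sprintf("<classification_scheme> %d source classes -> %d DLCT\n",
              nrow(x$source_classes), nrow(x$dlct_classes)))
  print(x$dlct_classes)
  invisible(x)
}

#' Default 10-class DLCT scheme
#'
#' The ten dominant land-cover types used throughout the package, with
#' default greenness weights. The CORINE-style 44-to-10 aggregation table is
#' a configurable default (the authoritative national aggregation is not
#' standardised); see [read_scheme()] to supply your own as YAML.
#'
#' DLCT codes: 1 artificial, 2 arable, 3 pasture & natural grassland,
#' 4 permanent crops & mosaics, 5 forest, 6 transitional woodland & shrub,
#' 7 sparsely vegetated & bare, 8 wetland, 9 water body, 10 glacier &
#' perpetual snow.
#'
#' @return A `classification_scheme` whose source classes are the DLCT
#'   themselves (identity mapping); combine with a source nomenclature via
#'   [read_scheme()] for detailed inputs.
#' @export
default_scheme <- function() {
  dlct <- data.frame(
    code = 1:10,
    name = c("artificial", "arable", "pasture_grassland", "permanent_crops",
             "forest", "transitional_woodland_shrub", "sparse_bare",
             "wetland", "water_body", "glacier_snow"))
  gw <- c(`1` = 0, `2` = 0.3, `3` = 0.6, `4` = 0.5, `5` = 1.0, `6` = 0.8,
          `7` = 0.2, `8` = 0.9, `9` = 0.8, `10` = 0.1)
  mapping <- stats::setNames(as.integer(dlct$code), as.character(dlct$code))
  classification_scheme(dlct, dlct, mapping, gw)
}

#' Read / write a classification scheme as YAML
#'
#' Format: top-level keys `source_classes` (list of `{code, name}`),
#' `dlct_classes` (idem), `mapping` (map source code -> dlct code),
#' `green_weight` (map dlct code -> weight).
#'
#' @param path File path.
#' @return `read_scheme()` returns a `classification_scheme`;
#'   `write_scheme()` returns `path` invisibly.
#' @export
read_scheme <- function(path) {
  y <- yaml::read_yaml(path)
  sc <- do.call(rbind, lapply(y$source_classes, as.data.frame))
  dc <- do.call(rbind, lapply(y$dlct_classes, as.data.frame))
  classification_scheme(sc, dc,
                        unlist(y$mapping),
                        unlist(y$green_weight))
}

#' @rdname read_scheme
#' @param scheme A `classification_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  y <- list(
    source_classes = lapply(seq_len(nrow(scheme$source_classes)), function(i)
      as.list(scheme$source_classes[i, c("code", "name")])),
    dlct_classes = lapply(seq_len(nrow(scheme$dlct_classes)), function(i)
      as.list(scheme$dlct_classes[i, c("code", "name")])),
    mapping = as.list(scheme$mapping),
    green_weight = as.list(scheme$green_weight))
  yaml::write_yaml(y, path)
  invisible(path)
}
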