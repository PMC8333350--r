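#' Default Desikan-Killiany + Aseg region atlas
#'
#' The canonical 101-region atlas used throughout the package: the 68
#' Desikan-Killiany cortical subregions (34 per hemisphere, prefixed
#' \code{lh_}/\code{rh_}) followed by 33 Aseg neuroanatomical structures
#' (14 bilateral pairs plus 5 midline structures). The list is a canonical
#' reconstruction of the standard FreeSurfer output tables; region order is
#' significant and shared by every cohort in one analysis.
#'
#' @return A data.frame with columns \code{name} (unique region identifier),
#'   \code{kind} (\code{"cortical"} or \code{"subcortical"}; the subcortical
#'   kind covers both grey-matter structures and ventricular spaces) and
#'   \code{hemi} (\code{"lh"}, \code{"rh"} or \code{"mid"}).
#' @examples
#' atlas <- dkAsegAtlas()
#' nrow(atlas)            # 101
#' table(atlas$kind)      # 68 cortical, 33 subcortical
#' @export
dkAsegAtlas <- function() {
  dk <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
    "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
    "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
    "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
    "postcentral", "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
    "temporalpole", "transversetemporal", "insula")
  aseg_pairs <- c(
    "Lateral-Ventricle", "Inf-Lat-Vent", "Cerebellum-White-Matter",
    "Cerebellum-Cortex", "Thalamus-Proper", "Caudate", "Putamen", "Pallidum",
    "Hippocampus", "Amygdala", "Accumbens-area", "VentralDC", "vessel",
    "choroid-plexus")
  aseg_mid <- c("3rd-Ventricle", "4th-Ventricle", "Brain-Stem", "CSF",
                "Optic-Chiasm")
  name <- c(paste0("lh_", dk), paste0("rh_", dk),
            paste0("Left-", aseg_pairs), paste0("Right-", aseg_pairs),
            aseg_mid)
  kind <- c(rep("cortical", 68L), rep("subcortical", 33L))
  hemi <- c(rep("lh", 34L), rep("rh", 34L), rep("lh", 14L), rep("rh", 14L),
            rep("mid", 5L))
  data.frame(name = name, kind = kind, hemi = hemi,
             stringsAsFactors = FALSE)
}

#' Read a user-supplied atlas file
#'
#' Plain-text atlas dialect: one region name per line, order significant.
#' Region kind is inferred from the FreeSurfer naming convention
#' (\code{lh_}/\code{rh_} prefix = cortical, otherwise subcortical).
#'
#' @param path Path to a text file with one region name per line.
#' @return A data.frame as returned by [dkAsegAtlas()].
#' @export
readAtlas <- function(path) {
  nm <- readLines(path, warn = FALSE)
  nm <- trimws(nm)
  nm <- nm[nzchar(nm)]
  if (anyDuplicated(nm))
    stop("atlas file contains duplicated region names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  cortical <- grepl("^(lh|rh)_", nm)
  hemi <- ifelse(grepl("^(lh_|Left-)", nm), "lh",
                 ifelse(grepl("^(rh_|Right-)", nm), "rh", "mid"))
  data.frame(name = nm,
             kind = ifelse(cortical, "cortical", "subcortical"),
             hemi = hemi, stringsAsFactors = FALSE)
}

checkAtlas <- function(atlas) {
  stopifnot(is.data.frame(atlas), all(c("name", "kind") %in% names(atlas)))
  if (anyDuplicated(atlas$name))
    stop("atlas region names must be unique")
  invisible(atlas)
}
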