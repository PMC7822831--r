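# 10-10 montage: 63 analysis channels (64-channel cap referenced to Cz),
# with the cortical area x hemisphere grouping used for regional TRP
# aggregation. Midline channels and the lowest lateral ring (FT9/FT10,
# TP9/TP10) belong to no area group and never enter regional statistics.

# Area membership per hemisphere. The left lists are the published grouping;
# the right lists mirror them electrode-for-electrode (FC3 <-> FC4,
# FC5 <-> FC6), which keeps the ten groups a partition with sizes
# (9, 4, 5, 4, 4) per hemisphere.
.area_groups <- list(
  frontal   = list(left = c("Fp1", "AF3", "AF7", "F1", "F3", "F5", "F7", "FC1", "FC3"),
                   right = c("Fp2", "AF4", "AF8", "F2", "F4", "F6", "F8", "FC2", "FC4")),
  central   = list(left = c("FC5", "C1", "C3", "C5"),
                   right = c("FC6", "C2", "C4", "C6")),
  temporal  = list(left = c("FT7", "T7", "TP7", "CP5", "P5"),
                   right = c("FT8", "T8", "TP8", "CP6", "P6")),
  parietal  = list(left = c("CP1", "CP3", "P1", "P3"),
                   right = c("CP2", "CP4", "P2", "P4")),
  occipital = list(left = c("PO3", "PO7", "P7", "O1"),
                   right = c("PO4", "PO8", "P8", "O2"))
)

.midline_channels <- c("AFz", "Fz", "FCz", "CPz", "Pz", "POz", "Oz")
.extra_lateral    <- c("FT9", "FT10", "TP9", "TP10")

# Schematic 10-10 grid position for a label: anterior-posterior ring index y
# (Fp = 4 ... O = -4) and lateral index x (z = 0; odd numbers left, even
# right; 1/2 -> 1 step ... 9/10 -> 5 steps).
.grid_pos <- function(name) {
  m <- regmatches(name, regexec("^([A-Za-z]+?)(z|[0-9]+)$", name))[[1]]
  if (length(m) == 0L) stop("unrecognized channel label: ", name)
  ring <- m[2]
  num <- m[3]
  y <- switch(ring,
              Fp = 4, AF = 3, F = 2, FT = 1, FC = 1, C = 0, T = 0,
              TP = -1, CP = -1, P = -2, PO = -3, O = -4,
              stop("unrecognized ring in channel label: ", name))
  if (num == "z") {
    x <- 0
  } else {
    n <- as.integer(num)
    step <- ceiling(n / 2)
    x <- if (n %% 2 == 1L) -step else step
  }
  # temporal-line labels (T7, FT7, TP7 ...) sit on the 4th/5th lateral step
  c(x = x, y = y)
}

#' Construct the fixed 63-channel analysis montage
#'
#' Returns the 10-10 montage of a 64-channel cap referenced to Cz: 63 analysis
#' channels with unit-sphere positions, cortical area labels (frontal,
#' central, temporal, parietal, occipital, or none) and hemisphere labels
#' (left, right, midline). The ten area-by-hemisphere groups contain exactly
#' 52 electrodes, (9, 4, 5, 4, 4) per hemisphere; midline channels and the
#' low lateral ring carry area `"none"` and are excluded from regional
#' aggregation.
#'
#' Positions are schematic 10-10 spherical coordinates (18 degrees of polar
#' angle per 10% step from the vertex), sufficient for neighbour weighting
#' and synthetic topography construction; they are not digitized positions.
#'
#' @param area_groups Optional replacement for the area-by-hemisphere channel
#'   grouping, a named list like the default (areas, each with `left`/`right`
#'   character vectors). Exposed because the published grouping admits
#'   alternative resolutions of its duplicated right-hemisphere entry.
#' @return An object of class `eeg_montage`: a data frame with columns
#'   `channel`, `x`, `y`, `z` (unit sphere; x right, y anterior, z up),
#'   `area`, `hemisphere`.
#' @examples
#' m <- make_montage()
#' nrow(m)                      # 63
#' subset(m, area == "frontal" & hemisphere == "left")$channel
#' @export
make_montage <- function(area_groups = NULL) {
  groups <- area_groups %||% .area_groups
  grouped <- unlist(lapply(groups, unlist), use.names = FALSE)
  if (anyDuplicated(grouped))
    stop("area groups must not share channels: ",
         paste(grouped[duplicated(grouped)], collapse = ", "))
  channels <- c(grouped, .midline_channels, .extra_lateral)
  channels <- channels[!duplicated(channels)]

  area <- rep("none", length(channels))
  hemi <- rep(NA_character_, length(channels))
  names(area) <- names(hemi) <- channels
  for (a in names(groups)) {
    for (side in c("left", "right")) {
      area[groups[[a]][[side]]] <- a
      hemi[groups[[a]][[side]]] <- side
    }
  }
  hemi[.midline_channels] <- "midline"
  hemi[c("FT9", "TP9")] <- "left"
  hemi[c("FT10", "TP10")] <- "right"

  g <- t(vapply(channels, .grid_pos, numeric(2)))
  r <- sqrt(g[, 1]^2 + g[, 2]^2)
  theta <- pmin(r * 18, 115) * pi / 180   # polar angle from vertex
  phi <- atan2(g[, 1], g[, 2])            # azimuth, 0 = nasion
  out <- data.frame(
    channel = channels,
    x = sin(theta) * sin(phi),
    y = sin(theta) * cos(phi),
    z = cos(theta),
    area = unname(area),
    hemisphere = unname(hemi),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("eeg_montage", "data.frame")
  out
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("10-10 EEG montage: %d channels, %d in area groups\n",
              nrow(x), sum(x$area != "none")))
  tab <- table(x$area[x$area != "none"], x$hemisphere[x$area != "none"])
  print(tab)
  invisible(x)
}

#' List the channels of one area-by-hemisphere group
#'
#' @param montage An [make_montage()] object.
#' @param area One of `"frontal"`, `"central"`, `"temporal"`, `"parietal"`,
#'   `"occipital"`.
#' @param hemisphere `"left"` or `"right"`.
#' @return Character vector of channel names.
#' @export
montage_group <- function(montage, area, hemisphere) {
  sel <- montage$channel[montage$area == area & montage$hemisphere == hemisphere]
  if (length(sel) == 0L) stop("empty montage group: ", area, "/", hemisphere)
  sel
}

#' Write / read a montage as CSV
#'
#' Columns: name, x, y, z, area, hemisphere.
#' @param montage An `eeg_montage`.
#' @param path File path.
#' @return `read_montage_csv` returns an `eeg_montage`.
#' @export
write_montage_csv <- function(montage, path) {
  df <- montage
  names(df)[names(df) == "channel"] <- "name"
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_montage_csv
#' @export
read_montage_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "name"] <- "channel"
  class(df) <- c("eeg_montage", "data.frame")
  df
}
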