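# 10-20 / 10-10 montage handling: label parsing, schematic spherical
# coordinates, and the azimuthal-equidistant 2D projection used for
# electrode-plane construction and montage CSV import.

ROW_LETTERS <- c("Fp" = 1, "AF" = 2, "F" = 3, "FC" = 4, "C" = 5,
                 "CP" = 6, "P" = 7, "PO" = 8, "O" = 9)
# FT/T/TP are the lateral members of the FC/C/CP rows
ROW_ALIAS <- c("FT" = 4, "T" = 5, "TP" = 6)

#' Parse a 10-20 electrode label
#'
#' Decomposes a label such as `"FC3"` into its anterior-posterior row index
#' (1 = Fp row .. 9 = O row) and left-right column index (1..9, odd digits on
#' the left, `z` = 5, even digits on the right). `FT`/`T`/`TP` labels map to
#' the FC/C/CP rows.
#'
#' @param channels character vector of labels.
#' @return data.frame with columns `channel`, `row`, `col`.
#' @export
parse_1020 <- function(channels) {
  m <- regmatches(channels,
                  regexec("^(Fp|AF|FC|FT|CP|TP|PO|F|C|T|P|O)(z|[1-8])$",
                          channels, ignore.case = FALSE))
  bad <- channels[vapply(m, length, integer(1)) == 0L]
  if (length(bad))
    stop("channel(s) not in the built-in 10-20 coordinate table: ",
         paste(bad, collapse = ", "))
  row <- vapply(m, function(g) {
    p <- g[2L]
    unname(if (p %in% names(ROW_ALIAS)) ROW_ALIAS[p] else ROW_LETTERS[p])
  }, numeric(1))
  col <- vapply(m, function(g) {
    s <- g[3L]
    if (s == "z") return(5)
    d <- as.integer(s)
    if (d %% 2 == 1) 5 - (d + 1) / 2 else 5 + d / 2
  }, numeric(1))
  data.frame(channel = channels, row = row, col = col,
             stringsAsFactors = FALSE)
}

#' Schematic 10-20 coordinates and scalp projection
#'
#' Electrodes are placed on a unit sphere by the equal-angle 10-10
#' construction (18 degrees per 10% step along the nasion-inion and
#' left-right arcs) and flattened with the azimuthal-equidistant projection
#' (planar radius equal to the angle from the vertex, in radians). The
#' layout is left-right symmetric with the midline at `x = 0` and anterior
#' electrodes at positive `y`.
#'
#' @param channels character vector of 10-20 labels.
#' @return data.frame with `channel`, `theta` (inclination from the vertex,
#'   degrees), `phi` (azimuth from the right ear, counterclockwise, degrees),
#'   and projected plane coordinates `x`, `y`.
#' @export
montage_positions <- function(channels) {
  p <- parse_1020(channels)
  alpha <- (5 - p$row) * 18 * pi / 180      # anterior-posterior angle
  beta  <- (p$col - 5) * 18 * pi / 180      # left-right angle
  vx <- sin(beta)
  vy <- cos(beta) * sin(alpha)
  vz <- cos(beta) * cos(alpha)
  theta <- acos(pmin(1, pmax(-1, vz)))
  hyp <- sqrt(vx^2 + vy^2)
  px <- ifelse(hyp < 1e-12, 0, theta * vx / hyp)
  py <- ifelse(hyp < 1e-12, 0, theta * vy / hyp)
  data.frame(channel = p$channel,
             theta = theta * 180 / pi,
             phi = atan2(vy, vx) * 180 / pi,
             x = px, y = py, stringsAsFactors = FALSE)
}

#' Built-in montages
#'
#' * `"standard_1010"`: 57-channel 10-10 cap (rows Fp/AF/F/FC/C/CP/P/PO/O).
#' * `"sensorimotor_30"`: the 30-channel montage emitted by the synthetic
#'   force-MI generator (includes FC3, FCz, FC4, C3, Cz, C4).
#' * `"bci_iv_2a"`: the 22-channel four-class MI benchmark montage.
#' * `"sensorimotor_18"`: compact 18-channel sensorimotor montage used by the
#'   scaled-down decoding benchmark.
#'
#' @param name montage name.
#' @return character vector of channel names.
#' @export
montage_channels <- function(name = c("standard_1010", "sensorimotor_30",
                                      "bci_iv_2a", "sensorimotor_18")) {
  name <- match.arg(name)
  switch(name,
    standard_1010 = c(
      "Fp1", "Fpz", "Fp2",
      "AF3", "AFz", "AF4",
      "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
      "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
      "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
      "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
      "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
      "PO3", "POz", "PO4",
      "O1", "Oz", "O2"),
    sensorimotor_30 = c(
      "Fp1", "Fp2",
      "F7", "F3", "Fz", "F4", "F8",
      "FT7", "FC3", "FCz", "FC4", "FT8",
      "T7", "C3", "Cz", "C4", "T8",
      "TP7", "CP3", "CPz", "CP4", "TP8",
      "P7", "P3", "Pz", "P4", "P8",
      "O1", "Oz", "O2"),
    bci_iv_2a = c(
      "Fz",
      "FC3", "FC1", "FCz", "FC2", "FC4",
      "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
      "CP3", "CP1", "CPz", "CP2", "CP4",
      "P1", "Pz", "P2",
      "POz"),
    sensorimotor_18 = c(
      "F3", "Fz", "F4",
      "FC3", "FCz", "FC4",
      "T7", "C3", "Cz", "C4", "T8",
      "CP3", "CPz", "CP4",
      "P3", "Pz", "P4",
      "Oz"))
}

#' Read a montage CSV
#'
#' Expects columns `channel,theta,phi` with spherical angles in degrees
#' (`theta` = inclination from the vertex, `phi` = azimuth from the right
#' ear, counterclockwise). Returns projected plane coordinates via the
#' azimuthal-equidistant projection.
#'
#' @param path CSV file path.
#' @return data.frame with `channel`, `x`, `y`.
#' @export
read_montage_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel", "theta", "phi")
  if (!all(need %in% names(df)))
    stop("montage CSV must have columns channel,theta,phi")
  th <- df$theta * pi / 180
  ph <- df$phi * pi / 180
  data.frame(channel = df$channel, x = th * cos(ph), y = th * sin(ph),
             stringsAsFactors = FALSE)
}
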