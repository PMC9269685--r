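#' Supported depth-sensor models
#'
#' The package understands the joint vocabularies of three consumer depth
#' sensors with marker-less body tracking: the Microsoft Kinect V2 (Windows
#' Kinect SDK), the Microsoft Kinect Azure (Azure Kinect Body Tracking SDK)
#' and the Intel RealSense D435 tracked through the Nuitrack SDK. Each SDK
#' names its joint centers differently (e.g. the pelvis is `SpineBase` on the
#' V2, `Pelvis` on the Azure and `Waist` under Nuitrack).
#'
#' Only the upper-body joints entering transfer kinematics are declared; a
#' recording may contain any subset of the vocabulary.
#'
#' @format A character vector of sensor names.
#' @export
SENSOR_MODELS <- c("KINECT_V2", "KINECT_AZURE", "REALSENSE_NUITRACK")

# Per-SDK joint vocabularies (upper body). Matching elsewhere is
# case-insensitive with underscores stripped, so "SHOULDER_LEFT" == "ShoulderLeft".
SENSOR_VOCABULARIES <- list(
  KINECT_V2 = c(
    "SpineBase", "SpineMid", "SpineShoulder", "Neck", "Head",
    "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
    "ShoulderRight", "ElbowRight", "WristRight", "HandRight"
  ),
  KINECT_AZURE = c(
    "Pelvis", "SpineNavel", "SpineChest", "Neck", "Head",
    "ClavicleLeft", "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
    "ClavicleRight", "ShoulderRight", "ElbowRight", "WristRight", "HandRight"
  ),
  REALSENSE_NUITRACK = c(
    "Waist", "Torso", "Neck", "Head",
    "LeftCollar", "LeftShoulder", "LeftElbow", "LeftWrist", "LeftHand",
    "RightCollar", "RightShoulder", "RightElbow", "RightWrist", "RightHand"
  )
)

#' Canonical joint set used by the transfer features
#'
#' All four kinematic features are computed from five joint centers:
#' the pelvis, the upper spine (top of trunk), both shoulders and the
#' leading-side elbow.
#'
#' @export
CANONICAL_JOINTS <- c(
  "pelvis", "spine_upper", "shoulder_left", "shoulder_right", "elbow_left"
)

normalize_joint_name <- function(x) {
  tolower(gsub("[_ ]", "", x))
}

#' Construct a sensor model
#'
#' @param name One of `"KINECT_V2"`, `"KINECT_AZURE"`, `"REALSENSE_NUITRACK"`
#'   (short aliases `"v2"`, `"azure"`, `"realsense"` are accepted).
#' @param nominal_rate Nominal frame rate in frames per second. All three
#'   sensors stream skeletal data at up to 30 Hz.
#' @return A `sensor_model` object with fields `name`, `joint_vocabulary`
#'   and `nominal_rate`.
#' @examples
#' sensor_model("azure")
#' @export
sensor_model <- function(name, nominal_rate = 30) {
  aliases <- c(
    v2 = "KINECT_V2", kinectv2 = "KINECT_V2", kinect_v2 = "KINECT_V2",
    azure = "KINECT_AZURE", kinectazure = "KINECT_AZURE",
    kinect_azure = "KINECT_AZURE",
    realsense = "REALSENSE_NUITRACK", nuitrack = "REALSENSE_NUITRACK",
    realsense_nuitrack = "REALSENSE_NUITRACK"
  )
  key <- tolower(gsub("[ -]", "_", name))
  if (key %in% names(aliases)) name <- unname(aliases[[key]])
  name <- toupper(name)
  if (!name %in% SENSOR_MODELS) {
    stop("unsupported sensor model: ", name, call. = FALSE)
  }
  stopifnot(is.numeric(nominal_rate), nominal_rate > 0)
  structure(
    list(
      name = name,
      joint_vocabulary = SENSOR_VOCABULARIES[[name]],
      nominal_rate = nominal_rate
    ),
    class = "sensor_model"
  )
}

#' @export
print.sensor_model <- function(x, ...) {
  cat("<sensor_model>", x$name, "@", x$nominal_rate, "Hz\n")
  cat("  joints:", paste(x$joint_vocabulary, collapse = ", "), "\n")
  invisible(x)
}

# Resolve a user-supplied joint name against a vocabulary; returns the
# vocabulary spelling or NA.
match_joint <- function(name, vocabulary) {
  hit <- match(normalize_joint_name(name), normalize_joint_name(vocabulary))
  ifelse(is.na(hit), NA_character_, vocabulary[hit])
}
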