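# Travel-mode alphabets and classification groupings.
#
# The diary (ground-truth) alphabet is the full survey code list; the
# imputation alphabet is coarser because some distinctions (driver vs
# passenger, bus vs coach) are not observable from sensors alone.

#' Travel-mode alphabets
#'
#' `diary_modes()` returns the full mode code list used in ground-truth
#' diaries and validated timetables. `imputation_modes()` returns the coarser
#' alphabet the sensor-only imputation can emit, in the fixed order used for
#' deterministic tie-breaking.
#'
#' @return Character vector of mode codes.
#' @export
diary_modes <- function() {
  c("walk", "bike_roller_skateboard", "bus", "coach", "metro",
    "suburban_train", "tramway", "car_driver", "car_passenger",
    "long_distance_train", "plane", "jogging", "dog_walking",
    "ski_chairlift")
}

#' @rdname diary_modes
#' @export
imputation_modes <- function() {
  c("walk", "bike", "bus", "tramway", "metro", "suburban_train", "car",
    "long_distance")
}

# transit modes that carry station evidence
transit_modes <- function() c("bus", "tramway", "metro", "suburban_train")

#' Map diary mode codes onto the imputation alphabet
#'
#' Used when comparing imputed labels with ground truth: driver/passenger
#' collapse to `car`, bus and coach to `bus`, long-distance train and plane to
#' `long_distance`. Dog walking is walking as far as a sensor is concerned;
#' jogging and ski/chairlift keep their own (never-imputed) labels so they can
#' never count as agreement.
#'
#' @param mode character vector of diary mode codes.
#' @return character vector on the imputation alphabet.
#' @export
mode_to_imputation <- function(mode) {
  map <- c(
    walk = "walk", bike_roller_skateboard = "bike", bus = "bus",
    coach = "bus", metro = "metro", suburban_train = "suburban_train",
    tramway = "tramway", car_driver = "car", car_passenger = "car",
    long_distance_train = "long_distance", plane = "long_distance",
    jogging = "jogging", dog_walking = "walk", ski_chairlift = "ski_chairlift"
  )
  unknown <- setdiff(unique(mode), c(names(map), NA))
  if (length(unknown) > 0) {
    stop("unknown mode label(s): ", paste(unknown, collapse = ", "))
  }
  unname(map[mode])
}

crude_classes <- function() {
  c("entirely_walked", "other_active", "public_transport",
    "private_motorized", "other_long_distance", "multi_mode",
    "non_transport")
}

detailed_classes <- function() {
  c("entirely_walked", "other_active", "bus_coach", "metro",
    "suburban_train", "tramway", "private_motorized_driver",
    "private_motorized_passenger", "other_long_distance", "multi_mode",
    "non_transport")
}

# Group of a single non-walking mode under each scheme.  Jogging, dog walking
# and ski/chairlift are non-trip movement: they get their own group and are
# removed by the exclusion rules before any tabulation.
crude_group <- function(mode) {
  map <- c(
    bike_roller_skateboard = "other_active",
    bus = "public_transport", coach = "public_transport",
    metro = "public_transport", suburban_train = "public_transport",
    tramway = "public_transport",
    car_driver = "private_motorized", car_passenger = "private_motorized",
    long_distance_train = "other_long_distance", plane = "other_long_distance",
    jogging = "non_transport", dog_walking = "non_transport",
    ski_chairlift = "non_transport"
  )
  unknown <- setdiff(unique(mode), names(map))
  if (length(unknown) > 0) {
    stop("unknown mode label(s): ", paste(unknown, collapse = ", "))
  }
  unname(map[mode])
}

detailed_group <- function(mode) {
  map <- c(
    bike_roller_skateboard = "other_active",
    bus = "bus_coach", coach = "bus_coach",
    metro = "metro", suburban_train = "suburban_train", tramway = "tramway",
    car_driver = "private_motorized_driver",
    car_passenger = "private_motorized_passenger",
    long_distance_train = "other_long_distance", plane = "other_long_distance",
    jogging = "non_transport", dog_walking = "non_transport",
    ski_chairlift = "non_transport"
  )
  unknown <- setdiff(unique(mode), names(map))
  if (length(unknown) > 0) {
    stop("unknown mode label(s): ", paste(unknown, collapse = ", "))
  }
  unname(map[mode])
}
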