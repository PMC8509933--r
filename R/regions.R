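#' US Census Bureau region lookup
#'
#' Returns the standard four-region Census Bureau classification
#' (Northeast, Midwest, South, West) as a named character vector keyed by
#' two-letter state postal code. Covers the 50 states plus DC.
#'
#' @return Named character vector mapping state code to region name.
#' @examples
#' census_region_map()[["OH"]]  # "Midwest"
#' @export
census_region_map <- function() {
  c(
    CT = "Northeast", ME = "Northeast", MA = "Northeast", NH = "Northeast",
    RI = "Northeast", VT = "Northeast", NJ = "Northeast", NY = "Northeast",
    PA = "Northeast",
    IL = "Midwest", IN = "Midwest", MI = "Midwest", OH = "Midwest",
    WI = "Midwest", IA = "Midwest", KS = "Midwest", MN = "Midwest",
    MO = "Midwest", NE = "Midwest", ND = "Midwest", SD = "Midwest",
    DE = "South", FL = "South", GA = "South", MD = "South", NC = "South",
    SC = "South", VA = "South", DC = "South", WV = "South", AL = "South",
    KY = "South", MS = "South", TN = "South", AR = "South", LA = "South",
    OK = "South", TX = "South",
    AZ = "West", CO = "West", ID = "West", MT = "West", NV = "West",
    NM = "West", UT = "West", WY = "West", AK = "West", CA = "West",
    HI = "West", OR = "West", WA = "West"
  )
}

#' @keywords internal
region_levels <- function() c("Northeast", "Midwest", "South", "West")
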