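# Shared fixtures: the packaged Shenyang November 2016 month, the default
# standard-cloud set, and the published standard-cloud characteristics
# (two-decimal print precision) for all seven scales.

nov2016 <- shenyang_nov2016()
default_table <- default_grading_table()
std_set <- build_standard_clouds(default_table, k = 0.1)

published_standard_clouds <- local({
  cell <- function(indicator, level, ex, en, he)
    data.frame(indicator = indicator, level = level, ex = ex, en = en,
               he = he)
  rows <- list(
    cell("AQI",   1,   25,   8.33,  0.83), cell("AQI",   2,   75,   8.33,  0.83),
    cell("AQI",   3,  125,   8.33,  0.83), cell("AQI",   4,  175,   8.33,  0.83),
    cell("AQI",   5,  250,  16.67,  1.67),
    cell("PM2.5", 1, 17.5,   5.83,  0.58), cell("PM2.5", 2,   55,   6.67,  0.67),
    cell("PM2.5", 3,   95,   6.67,  0.67), cell("PM2.5", 4, 132.5,  5.83,  0.58),
    cell("PM2.5", 5,  200,  16.67,  1.67),
    cell("PM10",  1,   25,   8.33,  0.83), cell("PM10",  2,  100,  16.67,  1.67),
    cell("PM10",  3,  200,  16.67,  1.67), cell("PM10",  4,  300,  16.67,  1.67),
    cell("PM10",  5,  385,  11.67,  1.17),
    cell("SO2",   1,   25,   8.33,  0.83), cell("SO2",   2,  100,  16.67,  1.67),
    cell("SO2",   3, 312.5, 54.17,  5.42), cell("SO2",   4, 637.5, 54.17,  5.42),
    cell("SO2",   5, 1200, 133.33, 13.33),
    cell("CO",    1,    1,   0.33,  0.03), cell("CO",    2,    3,   0.33,  0.03),
    cell("CO",    3,    9,   1.67,  0.17), cell("CO",    4,   19,   1.67,  0.17),
    cell("CO",    5,   30,   2.00,  0.20),
    cell("NO2",   1,   20,   6.67,  0.67), cell("NO2",   2,   60,   6.67,  0.67),
    cell("NO2",   3,  130,  16.67,  1.67), cell("NO2",   4,  230,  16.67,  1.67),
    cell("NO2",   5, 422.5, 47.50,  4.75),
    cell("O3",    1,   50,  16.67,  1.67), cell("O3",    2,  130,  10.00,  1.00),
    cell("O3",    3, 187.5,  9.17,  0.92), cell("O3",    4,  240,   8.33,  0.83),
    cell("O3",    5, 532.5, 89.17,  8.92))
  do.call(rbind, rows)
})
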