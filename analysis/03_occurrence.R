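#!/usr/bin/env Rscript
# Step 3 — confirm occurrence grid cells and the area of occurrence.
#
# A 10x10 km cell is confirmed for a monitoring year by one C1 sign or two
# independent C2 signs. The area-of-occurrence trend is restricted to cells
# whose centre lies in the Alpine-range polygon (100 km2 per cell).

suppressMessages(library(wolfalps))

classified <- utils::read.csv("results/classified_signs.csv")
layout <- read_layout_geojson("results/synthetic/region.geojson")
years <- sort(unique(classified$monitoring_year))

rows <- list()
for (y in years) {
  map <- confirm_cells(classified, y)
  area <- area_of_occurrence(map, layout)
  cells <- map$cells
  if (nrow(cells)) {
    cells$monitoring_year <- y
    rows[[y]] <- cells
  }
  cat(sprintf("%s: %3d candidate cells, %3d confirmed, area of occurrence %6d km2\n",
              y, nrow(cells), sum(cells$confirmed), area))
  if (y == years[length(years)])
    write_occurrence_geojson(map, "results/occurrence_final_year.geojson")
}
utils::write.csv(do.call(rbind, rows), "results/occurrence.csv",
                 row.names = FALSE)
cat("Wrote results/occurrence.csv and results/occurrence_final_year.geojson\n")
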