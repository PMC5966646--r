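Package: silicrop
Title: Dynamic Simulation of Silicon Bioavailability and Uptake in Tomato
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A dynamic simulator of silicon nutrition for greenhouse tomato.
    Computes bioavailable orthosilicic acid (Si(OH)4) in the soil solution
    from soil temperature, organic-matter content and pH; drives dry-biomass
    accumulation and transpiration from photosynthetically active radiation,
    air temperature and CO2; and accumulates silicon (bookkept as SiO2) in
    the plant through the transpiration stream, capped at 1 percent of dry
    biomass and allocated to organs by their transpiration shares. Supports
    soil and soilless (hydroponic) cultivation scenarios, response-surface
    sweeps over edaphic and aerial factors, silicate species/unit
    conversions, a synthetic environment generator, and a command-line
    interface with CSV/JSON input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
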