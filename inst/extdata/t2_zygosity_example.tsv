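plant_id	locus_id	pcrA	pcrB
plant01	chr15_982591	+	+
plant02	chr15_982591	+	-
plant03	chr15_982591	-	+
plant04	chr15_982591	+	+
plant05	chr15_982591	+	-
plant06	chr15_982591	-	+
plant07	chr15_982591	-	+
plant08	chr15_982591	+	-
plant09	chr15_982591	+	+
plant10	chr15_982591	+	-
plant11	chr15_982591	+	+
plant12	chr15_982591	+	+
plant13	chr15_982591	-	+
plant14	chr15_982591	-	+
plant15	chr15_982591	+	-
plant16	chr15_982591	+	+
plant17	chr15_982591	+	+
plant18	chr15_982591	+	-
plant19	chr15_982591	+	+
plant01	chr18_7461224	+	+
plant02	chr18_7461224	+	-
plant03	chr18_7461224	+	-
plant04	chr18_7461224	+	+
plant05	chr18_7461224	+	+
plant06	chr18_7461224	+	+
plant07	chr18_7461224	+	-
plant08	chr18_7461224	+	+
plant09	chr18_7461224	+	-
plant10	chr18_7461224	+	+
plant11	chr18_7461224	+	-
plant12	chr18_7461224	+	+
plant13	chr18_7461224	+	+
plant14	chr18_7461224	+	+
plant15	chr18_7461224	+	+
plant16	chr18_7461224	+	+
plant17	chr18_7461224	+	-
plant18	chr18_7461224	+	-
plant19	chr18_7461224	+	+
plant01	chr8_24442089	+	+
plant02	chr8_24442089	+	+
plant03	chr8_24442089	+	+
plant04	chr8_24442089	+	+
plant05	chr8_24442089	+	+
plant06	chr8_24442089	+	+
plant07	chr8_24442089	+	+
plant08	chr8_24442089	+	+
plant09	chr8_24442089	+	+
plant10	chr8_24442089	+	+
plant11	chr8_24442089	+	+
plant12	chr8_24442089	+	+
plant13	chr8_24442089	+	+
plant14	chr8_24442089	+	+
plant15	chr8_24442089	+	+
plant16	chr8_24442089	+	+
plant17	chr8_24442089	+	+
plant18	chr8_24442089	+	+
plant19	chr8_24442089	+	+
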