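gene_name	chrom	start	end	strand	frame	n_premature_stops	first_stop_nt
ADAM9	chr8	39018918	39021642	+	1	59	73
DDX39A	chr19	14409447	14409535	-	2	2	2
GGA3	chr17	75240108	75240341	-	1	3	19
HAX1	chr1	154273598	154273773	+	3	2	57
LIG3	chr17	34991837	34991957	+	2	1	41
MAPK10	chr4	86098595	86101051	-	3	57	39
MROH1	chr8	144260544	144260676	+	1	0	NA
NECAP1	chr12	8091850	8092675	+	2	12	2
PDHB	chr3	58431793	58431876	-	1	0	NA
POLG	chr15	89318749	89318930	-	1	1	130
TBC1D20	chr20	441689	441856	-	2	3	8
ENSG00000271793	chr6	85547397	85547505	-	1	1	40
ENSG00000284946	chr15	90981033	90981498	-	1	16	25
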