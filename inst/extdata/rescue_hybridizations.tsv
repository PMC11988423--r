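class	gene_name	mirna_id	delta_psi_contrast1	delta_psi_contrast2	mfe
A5SS	POLR2J3	hsa-miR-134-5p	0.136	-0.127	-30.3
RI	ENSG00000284946	hsa-miR-877-5p	0.113	-0.12	-31.9
RI	NECAP1	hsa-miR-628-3p	0.194	-0.159	-32.5
RI	MAPK10	hsa-miR-744-5p	-0.217	0.244	-40.5
RI	POLG	hsa-miR-328-3p	0.278	-0.233	-37.1
RI	POLG	hsa-miR-423-3p	0.278	-0.233	-38.4
RI	POLG	hsa-miR-874-3p	0.278	-0.233	-35.7
RI	POLG	hsa-miR-1249-3p	0.278	-0.233	-32.8
RI	MROH1	hsa-miR-328-3p	-0.351	0.351	-34.8
RI	MROH1	hsa-miR-331-3p	-0.351	0.351	-34.8
RI	MROH1	hsa-miR-874-3p	-0.351	0.351	-35.5
A3SS	TYK2	hsa-miR-328-3p	-0.458	0.458	-34.1
A3SS	TYK2	hsa-miR-874-3p	-0.458	0.458	-42.4
A3SS	TYK2	hsa-miR-1249-3p	-0.458	0.458	-32.9
A3SS	TYK2	hsa-miR-3200-3p	-0.458	0.458	-31.3
A3SS	GTF2IRD1	hsa-miR-185-5p	-0.328	0.221	-30.7
SE	FBXL20	hsa-miR-671-5p	-0.15	0.171	-32.6
SE	APBA2	hsa-miR-145-5p	-0.134	0.151	-30
SE	APBA2	hsa-miR-328-3p	-0.134	0.151	-31.7
SE	APBA2	hsa-miR-370-3p	-0.134	0.151	-41
SE	APBA2	hsa-miR-744-5p	-0.134	0.151	-39.6
SE	APBA2	hsa-miR-1301-3p	-0.134	0.151	-30.9
SE	CHRNA7	hsa-miR-149-5p	-0.242	0.242	-33.3
SE	FBXW4	hsa-miR-874-3p	-0.13	0.146	-35.4
SE	HIP1	hsa-miR-145-5p	-0.149	0.149	-32
SE	HIP1	hsa-miR-423-3p	-0.149	0.149	-35.3
SE	HIP1	hsa-miR-1180-3p	-0.149	0.149	-32.5
SE	LAMB1	hsa-miR-744-5p	-0.167	0.151	-31.1
SE	BCL2L13	hsa-miR-185-5p	-0.209	0.246	-31.4
SE	ZC3H4	hsa-miR-149-5p	-0.234	0.234	-31
SE	ZC3H4	hsa-miR-328-3p	-0.234	0.234	-31.1
SE	MVK	hsa-miR-652-3p	-0.297	0.297	-30.2
SE	MVK	hsa-miR-874-3p	-0.297	0.297	-34.3
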