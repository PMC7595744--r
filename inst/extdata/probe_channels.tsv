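channel_id	source_id	detector_id	nominal_separation_mm	midpoint_x	midpoint_y	axis_x	axis_y
C001	S01	D01	15	-57.5	4	1	0
C002	S02	D02	15	-52.5	4	0.7071067812	0.7071067812
C003	S03	D03	15	-47.5	4	0	1
C004	S04	D04	15	-42.5	4	-0.7071067812	0.7071067812
C005	S05	D05	15	-37.5	4	1	0
C006	S06	D06	15	-32.5	4	0.7071067812	0.7071067812
C007	S07	D07	15	-27.5	4	0	1
C008	S08	D08	15	-22.5	4	-0.7071067812	0.7071067812
C009	S09	D09	15	-17.5	4	1	0
C010	S10	D10	15	-12.5	4	0.7071067812	0.7071067812
C011	S11	D11	15	-7.5	4	0	1
C012	S12	D12	15	-2.5	4	-0.7071067812	0.7071067812
C013	S01	D13	15	2.5	4	1	0
C014	S02	D14	15	7.5	4	0.7071067812	0.7071067812
C015	S03	D15	15	12.5	4	0	1
C016	S04	D01	15	17.5	4	-0.7071067812	0.7071067812
C017	S05	D02	15	22.5	4	1	0
C018	S06	D03	15	27.5	4	0.7071067812	0.7071067812
C019	S07	D04	15	32.5	4	0	1
C020	S08	D05	15	37.5	4	-0.7071067812	0.7071067812
C021	S09	D06	15	42.5	4	1	0
C022	S10	D07	15	47.5	4	0.7071067812	0.7071067812
C023	S11	D08	15	52.5	4	0	1
C024	S12	D09	15	57.5	4	-0.7071067812	0.7071067812
C025	S01	D10	15	-57.5	12	1	0
C026	S02	D11	15	-52.5	12	0.7071067812	0.7071067812
C027	S03	D12	15	-47.5	12	0	1
C028	S04	D13	15	-42.5	12	-0.7071067812	0.7071067812
C029	S05	D14	15	-37.5	12	1	0
C030	S06	D15	15	-32.5	12	0.7071067812	0.7071067812
C031	S07	D01	15	-27.5	12	0	1
C032	S08	D02	15	-22.5	12	-0.7071067812	0.7071067812
C033	S09	D03	15	-17.5	12	1	0
C034	S10	D04	15	-12.5	12	0.7071067812	0.7071067812
C035	S11	D05	15	-7.5	12	0	1
C036	S12	D06	15	-2.5	12	-0.7071067812	0.7071067812
C037	S01	D07	15	2.5	12	1	0
C038	S02	D08	15	7.5	12	0.7071067812	0.7071067812
C039	S03	D09	15	12.5	12	0	1
C040	S04	D10	15	17.5	12	-0.7071067812	0.7071067812
C041	S05	D11	30	22.5	12	1	0
C042	S06	D12	30	27.5	12	0.7071067812	0.7071067812
C043	S07	D13	30	32.5	12	0	1
C044	S08	D14	30	37.5	12	-0.7071067812	0.7071067812
C045	S09	D15	30	42.5	12	1	0
C046	S10	D01	30	47.5	12	0.7071067812	0.7071067812
C047	S11	D02	30	52.5	12	0	1
C048	S12	D03	30	57.5	12	-0.7071067812	0.7071067812
C049	S01	D04	30	-57.5	20	1	0
C050	S02	D05	30	-52.5	20	0.7071067812	0.7071067812
C051	S03	D06	30	-47.5	20	0	1
C052	S04	D07	30	-42.5	20	-0.7071067812	0.7071067812
C053	S05	D08	30	-37.5	20	1	0
C054	S06	D09	30	-32.5	20	0.7071067812	0.7071067812
C055	S07	D10	30	-27.5	20	0	1
C056	S08	D11	30	-22.5	20	-0.7071067812	0.7071067812
C057	S09	D12	30	-17.5	20	1	0
C058	S10	D13	30	-12.5	20	0.7071067812	0.7071067812
C059	S11	D14	30	-7.5	20	0	1
C060	S12	D15	30	-2.5	20	-0.7071067812	0.7071067812
C061	S01	D01	36	2.5	20	1	0
C062	S02	D02	36	7.5	20	0.7071067812	0.7071067812
C063	S03	D03	36	12.5	20	0	1
C064	S04	D04	36	17.5	20	-0.7071067812	0.7071067812
C065	S05	D05	36	22.5	20	1	0
C066	S06	D06	36	27.5	20	0.7071067812	0.7071067812
C067	S07	D07	36	32.5	20	0	1
C068	S08	D08	36	37.5	20	-0.7071067812	0.7071067812
C069	S09	D09	36	42.5	20	1	0
C070	S10	D10	36	47.5	20	0.7071067812	0.7071067812
C071	S11	D11	36	52.5	20	0	1
C072	S12	D12	36	57.5	20	-0.7071067812	0.7071067812
C073	S01	D13	36	-57.5	28	1	0
C074	S02	D14	36	-52.5	28	0.7071067812	0.7071067812
C075	S03	D15	36	-47.5	28	0	1
C076	S04	D01	36	-42.5	28	-0.7071067812	0.7071067812
C077	S05	D02	36	-37.5	28	1	0
C078	S06	D03	36	-32.5	28	0.7071067812	0.7071067812
C079	S07	D04	36	-27.5	28	0	1
C080	S08	D05	36	-22.5	28	-0.7071067812	0.7071067812
C081	S09	D06	36	-17.5	28	1	0
C082	S10	D07	36	-12.5	28	0.7071067812	0.7071067812
C083	S11	D08	36	-7.5	28	0	1
C084	S12	D09	36	-2.5	28	-0.7071067812	0.7071067812
C085	S01	D10	36	2.5	28	1	0
C086	S02	D11	36	7.5	28	0.7071067812	0.7071067812
C087	S03	D12	36	12.5	28	0	1
C088	S04	D13	36	17.5	28	-0.7071067812	0.7071067812
C089	S05	D14	36	22.5	28	1	0
C090	S06	D15	36	27.5	28	0.7071067812	0.7071067812
C091	S07	D01	36	32.5	28	0	1
C092	S08	D02	36	37.5	28	-0.7071067812	0.7071067812
C093	S09	D03	45	42.5	28	1	0
C094	S10	D04	45	47.5	28	0.7071067812	0.7071067812
C095	S11	D05	45	52.5	28	0	1
C096	S12	D06	45	57.5	28	-0.7071067812	0.7071067812
C097	S01	D07	45	-57.5	36	1	0
C098	S02	D08	45	-52.5	36	0.7071067812	0.7071067812
C099	S03	D09	45	-47.5	36	0	1
C100	S04	D10	45	-42.5	36	-0.7071067812	0.7071067812
C101	S05	D11	45	-37.5	36	1	0
C102	S06	D12	45	-32.5	36	0.7071067812	0.7071067812
C103	S07	D13	45	-27.5	36	0	1
C104	S08	D14	45	-22.5	36	-0.7071067812	0.7071067812
C105	S09	D15	45	-17.5	36	1	0
C106	S10	D01	45	-12.5	36	0.7071067812	0.7071067812
C107	S11	D02	45	-7.5	36	0	1
C108	S12	D03	45	-2.5	36	-0.7071067812	0.7071067812
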