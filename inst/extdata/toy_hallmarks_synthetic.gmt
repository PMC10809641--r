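TOY_ESTROGEN_RESPONSE_EARLY	synthetic stand-in set	GENE0001	GENE0002	GENE0003	GENE0004	GENE0005	GENE0006	GENE0007	GENE0008	GENE0009	GENE0010
TOY_ESTROGEN_RESPONSE_LATE	synthetic stand-in set	GENE0006	GENE0007	GENE0008	GENE0011	GENE0012	GENE0013	GENE0014	GENE0015	GENE0016	GENE0017
TOY_UV_RESPONSE_DN	synthetic stand-in set	GENE0018	GENE0019	GENE0020	GENE0021	GENE0022	GENE0023	GENE0024	GENE0025	GENE0026	GENE0027
TOY_HYPOXIA	synthetic stand-in set	GENE0028	GENE0029	GENE0030	GENE0031	GENE0032	GENE0033	GENE0034	GENE0035	GENE0036	GENE0037
TOY_EMT	synthetic stand-in set	GENE0038	GENE0039	GENE0040	GENE0041	GENE0042	GENE0043	GENE0044	GENE0045	GENE0046	GENE0047
TOY_APOPTOSIS	synthetic stand-in set	GENE0048	GENE0049	GENE0050	GENE0051	GENE0052	GENE0053	GENE0054	GENE0055	GENE0056	GENE0057
TOY_INFLAMMATORY_RESPONSE	synthetic stand-in set	GENE0058	GENE0059	GENE0060	GENE0061	GENE0062	GENE0063	GENE0064	GENE0065	GENE0066	GENE0067
TOY_GLYCOLYSIS	synthetic stand-in set	GENE0068	GENE0069	GENE0070	GENE0071	GENE0072	GENE0073	GENE0074	GENE0075	GENE0076	GENE0077
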