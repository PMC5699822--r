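specimen_id,year_collected,preservation,loci_count,study
eth_01,2012,ethanol,466,weevils_synthetic
eth_02,2011,ethanol,531,weevils_synthetic
eth_03,2013,ethanol,561,weevils_synthetic
eth_04,2011,ethanol,407,weevils_synthetic
eth_05,2012,ethanol,369,weevils_synthetic
eth_06,2015,ethanol,567,weevils_synthetic
eth_07,2011,ethanol,492,weevils_synthetic
eth_08,2014,ethanol,596,weevils_synthetic
eth_09,2013,ethanol,490,weevils_synthetic
eth_10,2015,ethanol,549,weevils_synthetic
eth_11,2013,ethanol,443,weevils_synthetic
eth_12,2015,ethanol,505,weevils_synthetic
eth_13,2016,ethanol,486,weevils_synthetic
eth_14,2009,ethanol,542,weevils_synthetic
eth_15,2013,ethanol,448,weevils_synthetic
eth_16,2016,ethanol,419,weevils_synthetic
eth_17,2011,ethanol,578,weevils_synthetic
eth_18,2010,ethanol,376,weevils_synthetic
eth_19,2012,ethanol,588,weevils_synthetic
eth_20,2011,ethanol,435,weevils_synthetic
eth_21,2015,ethanol,447,weevils_synthetic
eth_22,2013,ethanol,467,weevils_synthetic
eth_23,2013,ethanol,515,weevils_synthetic
eth_24,2009,ethanol,501,weevils_synthetic
eth_25,2011,ethanol,513,weevils_synthetic
eth_26,2015,ethanol,527,weevils_synthetic
eth_27,2013,ethanol,463,weevils_synthetic
eth_28,2009,ethanol,422,weevils_synthetic
eth_29,2010,ethanol,504,weevils_synthetic
eth_30,2012,ethanol,588,weevils_synthetic
eth_31,2010,ethanol,445,weevils_synthetic
eth_32,2009,ethanol,364,weevils_synthetic
eth_33,2014,ethanol,436,weevils_synthetic
eth_34,2009,ethanol,591,weevils_synthetic
eth_35,2011,ethanol,529,weevils_synthetic
eth_36,2009,ethanol,356,weevils_synthetic
eth_37,2012,ethanol,502,weevils_synthetic
eth_38,2016,ethanol,487,weevils_synthetic
eth_39,2012,ethanol,528,weevils_synthetic
pin_01,1965,pinned,244,weevils_synthetic
pin_02,1969,pinned,368,weevils_synthetic
pin_03,1975,pinned,370,weevils_synthetic
pin_04,1977,pinned,368,weevils_synthetic
pin_05,1978,pinned,439,weevils_synthetic
pin_06,1989,pinned,543,weevils_synthetic
pin_07,1990,pinned,326,weevils_synthetic
pin_08,2000,pinned,545,weevils_synthetic
pin_09,2002,pinned,545,weevils_synthetic
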