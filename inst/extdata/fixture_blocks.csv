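id,lat,lon,population,tpu_id,dc_id,area_km2
SB0001,22.3271332275923,114.19085496046239,5166,T15,D04,2.6151355068576128
SB0002,22.31195113159557,114.1904296895133,3224,T11,D04,4.576487137000822
SB0003,22.310839288528708,114.20155920515988,274,T11,D04,4.576487137000822
SB0004,22.264496353308743,114.18236993098668,3768,T07,D02,3.661189709600658
SB0005,22.254085140893967,114.18345713734385,2236,T07,D02,3.661189709600658
SB0006,22.315057902894118,114.21469936740884,3479,T11,D04,4.576487137000822
SB0007,22.32535800579473,114.22186237882802,4778,T16,D04,6.10198284933443
SB0008,22.336726364364065,114.19122458722273,9193,T15,D04,2.6151355068576128
SB0009,22.341081684441455,114.18711849943173,1677,T15,D04,2.6151355068576128
SB0010,22.326197443847082,114.19864553348171,8505,T15,D04,2.6151355068576128
SB0011,22.254401103846348,114.17694582997497,3925,T06,D01,18.30594854800329
SB0012,22.244763384150822,114.19138099437758,6885,T07,D02,3.661189709600658
SB0013,22.32940289994251,114.21424887842282,6266,T15,D04,2.6151355068576128
SB0014,22.322362309665447,114.22120628057333,5340,T16,D04,6.10198284933443
SB0015,22.258962508684814,114.18419906799987,1302,T07,D02,3.661189709600658
SB0016,22.330969235829855,114.21199356489791,2791,T15,D04,2.6151355068576128
SB0017,22.262672290436676,114.19222340242924,4940,T07,D02,3.661189709600658
SB0018,22.322561148068985,114.22112468967615,1399,T16,D04,6.10198284933443
SB0019,22.329689989660697,114.21758460225779,1943,T15,D04,2.6151355068576128
SB0020,22.31796359074329,114.19764542289869,4775,T11,D04,4.576487137000822
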