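id,lat,lon,area_m2,activity_spaces,children_playground,water_features,wildlife_gardens,trees,walking_path,public_art,public_toilets,car_parking,barbeque,ndvi_mean,ai
P0001,22.32460951976478,114.18563785769045,13165.563380615864,0,1,0,1,1,1,1,1,1,1,0.21859290363864153,76.85
P0002,22.263110560290514,114.12872891828417,11136.68661307667,1,1,1,1,0,1,0,1,1,0,0.11904095509696486,73.14999999999999
P0003,22.30857485886663,114.17230183910578,26200.00644856491,0,1,1,1,1,1,1,0,1,0,0.303009668021942,82.99999999999999
P0004,22.324132006838916,114.15072853628546,1589.3485390620435,0,1,0,0,0,1,1,0,0,0,0.0889659109577074,28.325000000000003
P0005,22.230059047043323,114.1185879472643,8611.58107584436,1,1,0,0,0,1,0,1,0,0,0.1926987193901103,34.975
P0006,22.204653731025754,114.12977634508162,26160.503610747164,1,1,1,1,1,1,1,1,1,0,0.4583981014878099,94.82499999999999
P0007,22.22171420753002,114.21675681546331,613.4857600041074,1,0,0,0,0,1,0,0,1,0,0.1235350487190115,28.325
P0008,22.30882626850158,114.16589953139425,892.6115498405143,0,1,0,0,0,0,0,0,0,0,0.031899831130276446,6.65
P0009,22.34957167260349,114.16624794907868,594.5069167889467,0,0,0,0,0,1,1,0,0,0,0.16284924763831166,21.675
P0010,22.288079053498805,114.17684962064028,363.76911710600604,0,0,0,0,0,1,0,0,0,0,0.07888768502032951,16.5
P0011,22.29628259766847,114.168399114497,3660.350554906607,0,1,1,0,1,1,0,1,0,0,0.29120809929046465,61.324999999999996
P0012,22.231519118100405,114.12183845762164,8648.549356836214,0,0,1,0,1,1,1,0,0,0,0.4287902383378289,54.675
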