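period,lon_deg,lon_min,lon_sec,lon_hem,lat_deg,lat_min,lat_sec,lat_hem
current,111,22,41,E,30,30,51,N
ssp245_2050s,111,15,19,E,30,55,49,N
ssp245_2070s,112,0,60,E,31,8,37,N
ssp585_2050s,111,58,19,E,31,7,6,N
ssp585_2070s,111,47,2,E,31,11,54,N
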