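animal_id,trip_id,time,dhi_km,regime,amplitude_m,julian_day
a1,trip001,2011-01-10T09:00:00Z,4.2,diurnal,1.25,10
a1,trip001,2011-01-10T10:00:00Z,5.1,diurnal,1.25,10
a1,trip001,2011-01-10T11:00:00Z,6.0,diurnal,1.25,10
a1,trip002,2011-01-12T09:00:00Z,8.9,semidiurnal,0.95,12
a1,trip002,2011-01-12T10:00:00Z,9.4,semidiurnal,0.95,12
a1,trip002,2011-01-12T11:00:00Z,10.2,semidiurnal,0.95,12
a2,trip003,2011-01-14T09:00:00Z,5.9,diurnal,1.18,14
a2,trip003,2011-01-14T10:00:00Z,4.8,diurnal,1.18,14
a2,trip003,2011-01-14T11:00:00Z,5.2,diurnal,1.18,14
a2,trip004,2011-01-16T09:00:00Z,7.8,semidiurnal,1.02,16
a2,trip004,2011-01-16T10:00:00Z,8.6,semidiurnal,1.02,16
a2,trip004,2011-01-16T11:00:00Z,9.9,semidiurnal,1.02,16
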