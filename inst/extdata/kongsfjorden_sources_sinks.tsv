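# Published summer Sources-Sinks (delta_C, umol/kg) for Kongsfjorden,
# 2011-2020: pooled fjord water masses (IW, SW, fjord AW) contrasted against
# shelf Atlantic Water in the top 100 m. significant = water-mass means
# differ (two-tailed t-test, p < 0.05). fresh_conc is the freshwater
# endmember used (nitrate+nitrite: glacial-river mean 2.0 umol/kg; DIC:
# per-year salinity-regression intercept in Surface Water). Missing = NA.
tracer	year	pair	delta_C	significant	fresh_conc
nitrate_nitrite	2011	AWs_vs_IW	-2.0	TRUE	2.0
nitrate_nitrite	2011	AWs_vs_SW	-1.2	FALSE	2.0
nitrate_nitrite	2011	AWs_vs_AWf	NA	NA	2.0
nitrate_nitrite	2012	AWs_vs_IW	-4.9	FALSE	2.0
nitrate_nitrite	2012	AWs_vs_SW	-5.0	TRUE	2.0
nitrate_nitrite	2012	AWs_vs_AWf	-5.2	FALSE	2.0
nitrate_nitrite	2013	AWs_vs_IW	-3.7	FALSE	2.0
nitrate_nitrite	2013	AWs_vs_SW	-4.2	TRUE	2.0
nitrate_nitrite	2013	AWs_vs_AWf	-2.6	FALSE	2.0
nitrate_nitrite	2014	AWs_vs_IW	-4.7	TRUE	2.0
nitrate_nitrite	2014	AWs_vs_SW	-4.0	TRUE	2.0
nitrate_nitrite	2014	AWs_vs_AWf	-2.6	FALSE	2.0
nitrate_nitrite	2015	AWs_vs_IW	-7.5	TRUE	2.0
nitrate_nitrite	2015	AWs_vs_SW	-7.7	TRUE	2.0
nitrate_nitrite	2015	AWs_vs_AWf	-4.4	FALSE	2.0
nitrate_nitrite	2016	AWs_vs_IW	-5.3	TRUE	2.0
nitrate_nitrite	2016	AWs_vs_SW	-5.0	TRUE	2.0
nitrate_nitrite	2016	AWs_vs_AWf	-2.5	FALSE	2.0
nitrate_nitrite	2017	AWs_vs_IW	-3.3	FALSE	2.0
nitrate_nitrite	2017	AWs_vs_SW	-3.2	TRUE	2.0
nitrate_nitrite	2017	AWs_vs_AWf	0.5	FALSE	2.0
nitrate_nitrite	2018	AWs_vs_IW	-1.7	FALSE	2.0
nitrate_nitrite	2018	AWs_vs_SW	-1.8	FALSE	2.0
nitrate_nitrite	2018	AWs_vs_AWf	1.9	FALSE	2.0
nitrate_nitrite	2019	AWs_vs_IW	-4.0	FALSE	2.0
nitrate_nitrite	2019	AWs_vs_SW	-3.7	TRUE	2.0
nitrate_nitrite	2019	AWs_vs_AWf	-2.9	FALSE	2.0
nitrate_nitrite	2020	AWs_vs_IW	-4.7	TRUE	2.0
nitrate_nitrite	2020	AWs_vs_SW	-5.2	TRUE	2.0
nitrate_nitrite	2020	AWs_vs_AWf	-1.8	FALSE	2.0
dic	2012	AWs_vs_IW	-23.9	TRUE	668
dic	2012	AWs_vs_SW	-23.6	FALSE	668
dic	2012	AWs_vs_AWf	-17.4	FALSE	668
dic	2013	AWs_vs_IW	-13.1	TRUE	769
dic	2013	AWs_vs_SW	-4.6	FALSE	769
dic	2013	AWs_vs_AWf	26.0	FALSE	769
dic	2014	AWs_vs_IW	-34.5	TRUE	615
dic	2014	AWs_vs_SW	-28.3	TRUE	615
dic	2014	AWs_vs_AWf	-10.9	FALSE	615
dic	2015	AWs_vs_IW	-68.6	TRUE	1105
dic	2015	AWs_vs_SW	-72.8	TRUE	1105
dic	2015	AWs_vs_AWf	-5.1	FALSE	1105
dic	2017	AWs_vs_IW	-37.4	TRUE	1180
dic	2017	AWs_vs_SW	-41.9	TRUE	1180
dic	2017	AWs_vs_AWf	4.7	FALSE	1180
dic	2018	AWs_vs_IW	-14.4	TRUE	949
dic	2018	AWs_vs_SW	-23.9	TRUE	949
dic	2018	AWs_vs_AWf	28.9	FALSE	949
dic	2019	AWs_vs_IW	-27.9	TRUE	834
dic	2019	AWs_vs_SW	-38.9	TRUE	834
dic	2019	AWs_vs_AWf	-9.3	FALSE	834
dic	2020	AWs_vs_IW	-10.4	TRUE	555
dic	2020	AWs_vs_SW	-12.8	TRUE	555
dic	2020	AWs_vs_AWf	14.6	FALSE	555
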