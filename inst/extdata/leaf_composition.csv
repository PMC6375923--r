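compound_id,sample_id,mean_ug_g,sd_ug_g,censor
c01,CO-1,1933.2,36.9,none
c01,CO-2,1634.0,40.7,none
c01,CO-3,243.6,2.8,none
c01,CO-4,4238.1,33.9,none
c01,CO-5,1393.3,56.4,none
c01,CO-6,1091.5,17.9,none
c01,CO-7,14724.5,102.7,none
c01,CO-C,5612.6,228.5,none
c01,CP-1,2217.8,59.6,none
c01,CP-2,949.0,35.0,none
c01,CP-3,836.3,12.6,none
c01,CP-4,927.5,18.2,none
c01,CP-C,78.7,4.3,none
c01,CI-1,1644.1,44.7,none
c01,CI-2,323.4,12.8,none
c01,CI-3,1331.8,16.1,none
c01,CH-1,2881.9,74.0,none
c01,CH-2,993.4,110.6,none
c01,CHO-C,1492.6,8.3,none
c02,CO-1,181.4,4.0,none
c02,CO-2,277.6,14.5,none
c02,CO-3,33.3,1.7,none
c02,CO-6,40.2,1.5,none
c02,CO-C,83.2,0.4,none
c03,CO-1,455.7,9.8,none
c03,CO-2,884.0,11.1,none
c03,CO-3,196.9,3.0,none
c03,CO-5,284.5,6.3,none
c03,CO-6,69.7,1.3,none
c03,CO-C,612.2,9.7,none
c03,CI-1,1034.2,5.8,none
c03,CI-2,838.7,38.5,none
c03,CI-3,2066.8,28.8,none
c03,CHO-C,53.5,1.6,none
c04,CO-1,65.7,1.8,none
c04,CO-2,233.8,3.3,none
c04,CO-6,366.8,8.1,none
c04,CO-C,85.8,3.2,none
c04,CI-2,48.1,7.9,none
c04,CHO-C,295.0,3.6,none
c05,CO-1,105.1,10.5,none
c05,CO-2,370.2,11.5,none
c05,CO-C,204.2,12.2,none
c05,CP-C,22.4,1.2,none
c05,CI-1,67.2,8.2,none
c05,CI-2,43.0,4.3,none
c05,CI-3,112.4,1.6,none
c05,CHO-C,755.4,21.1,none
c06,CO-1,384.6,8.3,none
c06,CO-2,1077.7,10.2,none
c06,CO-3,40.2,3.3,none
c06,CO-4,6399.4,25.5,none
c06,CO-5,4187.9,119.8,none
c06,CO-6,160.9,1.5,none
c06,CO-7,5177.7,54.5,none
c06,CO-C,3661.7,74.0,none
c06,CP-1,1796.2,39.2,none
c06,CP-2,2127.9,54.4,none
c06,CP-3,1066.0,22.3,none
c06,CP-4,1993.5,20.3,none
c06,CP-C,187.7,1.2,none
c06,CI-1,491.7,4.0,none
c06,CI-2,652.9,39.9,none
c06,CI-3,2487.9,32.4,none
c06,CH-1,444.2,8.1,none
c06,CH-2,882.0,96.5,none
c06,CHO-C,1085.9,15.9,none
c07,CO-4,1117.6,9.7,none
c07,CO-5,1167.4,35.5,none
c07,CO-7,4523.8,44.9,none
c07,CP-1,1076.9,13.6,none
c07,CP-2,749.3,18.2,none
c07,CP-3,926.6,15.2,none
c07,CP-4,1562.5,19.4,none
c07,CP-C,24.1,0.9,none
c07,CHO-C,337.7,5.2,none
c08,CO-1,612.0,17.0,none
c08,CO-2,241.2,5.7,none
c08,CO-3,164.0,5.0,none
c08,CO-6,129.8,1.6,none
c08,CO-C,823.0,20.1,none
c08,CI-1,82.5,1.7,none
c08,CI-2,84.4,9.6,none
c09,CO-1,84.8,3.7,none
c09,CO-2,145.1,4.6,none
c09,CO-3,23.9,4.0,none
c09,CO-C,119.7,7.7,none
c09,CI-1,93.6,4.5,none
c09,CI-2,59.1,7.4,none
c09,CI-3,309.4,9.3,none
c09,CHO-C,79.1,1.1,none
c10,CO-1,240.4,6.7,none
c10,CO-2,465.3,8.4,none
c10,CO-3,269.6,2.4,none
c10,CO-5,112.1,7.4,none
c10,CO-6,315.3,8.4,none
c10,CO-C,118.3,5.9,none
c10,CI-1,86.9,2.0,none
c10,CI-2,47.9,1.7,none
c10,CHO-C,146.8,6.4,none
c11,CO-1,761.4,19.7,none
c11,CO-2,1671.4,26.2,none
c11,CO-3,1936.3,11.4,none
c11,CO-5,1044.7,36.3,none
c11,CO-6,2142.9,71.9,none
c11,CO-C,787.1,16.8,none
c11,CP-1,266.5,3.1,none
c11,CP-2,410.0,19.6,none
c11,CP-4,231.2,7.1,none
c11,CP-C,26.9,0.6,none
c11,CI-1,3213.6,61.0,none
c11,CI-2,2416.4,143.3,none
c11,CI-3,1677.5,23.8,none
c11,CHO-C,390.3,7.7,none
c12,CO-1,170.1,5.9,none
c12,CO-2,NA,NA,lod
c12,CO-5,98.0,1.3,none
c12,CO-7,295.2,3.6,none
c12,CP-1,198.2,2.1,none
c12,CP-2,457.4,37.2,none
c12,CP-3,625.2,2.5,none
c12,CP-4,457.3,2.7,none
c13,CO-1,156.2,4.1,none
c13,CO-2,511.8,6.5,none
c13,CO-3,80.6,1.5,none
c13,CO-6,233.4,3.0,none
c13,CO-C,138.8,4.3,none
c13,CP-C,42.4,2.6,none
c13,CI-1,110.5,17.1,none
c13,CI-2,79.5,13.3,none
c14,CO-1,58.0,1.0,none
c14,CO-2,134.1,1.9,none
c14,CI-1,73.0,1.1,none
c14,CI-2,102.1,5.9,none
c14,CI-3,237.0,4.3,none
c14,CHO-C,506.7,6.2,none
c15,CO-1,364.4,8.5,none
c15,CO-2,424.8,7.8,none
c15,CO-3,1057.6,5.2,none
c15,CO-5,1376.9,36.8,none
c15,CO-6,1356.7,30.8,none
c15,CP-1,1107.2,4.7,none
c15,CP-2,2338.1,103.2,none
c15,CP-3,3379.7,51.4,none
c15,CP-4,2132.5,25.3,none
c15,CI-1,587.1,7.2,none
c15,CI-2,672.4,18.2,none
c16,CO-1,177.7,5.1,none
c16,CO-2,436.9,5.2,none
c16,CO-3,287.5,2.5,none
c16,CO-6,179.1,4.7,none
c16,CI-1,329.4,8.4,none
c16,CI-2,219.5,21.0,none
c17,CO-4,502.8,2.3,none
c17,CO-7,991.2,12.1,none
c17,CP-C,121.2,1.3,none
c17,CI-3,795.6,12.5,none
c18,CO-3,38.1,0.7,none
c19,CP-3,338.3,14.2,none
c19,CP-C,21.2,0.6,none
c20,CO-4,318.8,1.4,none
c20,CO-5,251.0,59.2,none
c20,CP-1,457.8,11.1,none
c20,CP-2,444.2,4.5,none
c20,CP-4,540.9,3.4,none
c21,CO-4,1486.3,14.2,none
c21,CO-5,651.1,17.0,none
c21,CO-7,1622.9,16.7,none
c21,CP-1,426.8,3.4,none
c21,CP-2,631.3,24.1,none
c21,CP-3,314.0,31.6,none
c21,CP-4,332.4,3.9,none
c21,CH-1,144.9,3.6,none
c21,CH-2,173.6,20.7,none
c22,CP-3,244.2,69.0,none
c22,CP-4,70.4,0.4,none
c23,CP-2,172.1,12.0,none
c24,CO-C,124.9,1.7,none
c25,CO-4,657.8,6.7,none
c25,CO-5,171.3,4.5,none
c25,CP-2,141.4,6.2,none
c25,CP-3,196.3,2.5,none
c25,CP-4,58.5,1.5,none
c26,CO-7,696.2,4.1,none
c26,CP-1,148.4,12.4,none
c26,CP-2,614.9,23.4,none
c26,CP-3,478.5,5.4,none
c26,CP-4,116.6,1.1,none
c27,CO-4,939.7,18.9,none
c27,CO-C,2988.5,180.1,none
c27,CH-1,2884.2,102.9,none
c27,CH-2,1491.5,171.0,none
c28,CO-1,72.9,3.4,none
c28,CO-2,112.9,3.4,none
c28,CO-4,681.1,9.7,none
c28,CO-5,168.4,3.4,none
c28,CO-7,704.7,4.2,none
c28,CO-C,1041.2,25.1,none
c28,CP-C,53.5,1.2,none
c28,CH-1,3949.2,116.7,none
c28,CH-2,2105.6,218.6,none
c29,CO-4,352.1,20.6,none
c29,CO-C,519.2,98.6,none
c29,CP-4,294.9,9.0,none
c29,CI-1,127.4,2.8,none
c29,CI-2,93.3,2.5,none
c29,CI-3,800.7,21.2,none
c29,CH-1,1388.9,37.0,none
c29,CH-2,1105.2,121.7,none
c30,CO-C,655.6,3.8,none
c30,CP-1,524.8,19.9,none
c30,CP-2,161.3,4.5,none
c30,CP-C,23.9,0.8,none
c30,CI-1,453.0,8.2,none
c30,CI-2,248.1,5.0,none
c30,CI-3,825.8,28.4,none
c30,CH-1,4146.0,144.3,none
c30,CH-2,3957.0,43.0,none
c31,CH-1,226.9,7.5,none
c31,CH-2,165.5,18.4,none
c32,CO-C,423.5,8.0,none
c32,CI-3,215.7,8.1,none
c32,CH-1,1474.8,47.9,none
c32,CH-2,1040.1,115.2,none
c33,CH-1,240.1,17.1,none
c33,CH-2,179.1,25.3,none
c34,CO-1,202.6,18.0,none
c34,CO-2,241.1,22.0,none
c34,CO-3,144.1,8.1,none
c34,CO-5,205.6,9.0,none
c34,CO-6,510.2,2.9,none
c34,CO-7,138.5,13.2,none
c34,CO-C,98.0,6.8,none
c35,CO-1,799.1,NA,none
c35,CO-2,982.5,97.8,none
c35,CO-3,609.3,27.2,none
c35,CO-4,280.9,6.7,none
c35,CO-5,864.0,42.8,none
c35,CO-6,1857.1,61.8,none
c35,CO-7,653.0,40.6,none
c35,CO-C,688.8,44.0,none
c35,CP-3,260.3,17.1,none
c36,CO-7,57.1,8.0,none
c36,CO-C,121.3,6.0,none
c36,CP-4,213.9,8.0,none
c36,CI-1,179.1,4.5,none
c36,CI-2,227.8,20.3,none
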