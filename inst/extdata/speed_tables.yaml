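walking:
  forestland:
    mode: walking
    speed_kmh: 1.0
  grassland:
    mode: walking
    speed_kmh: 1.7
  cropland:
    mode: walking
    speed_kmh: 1.7
  settlement:
    mode: walking
    speed_kmh: 2.5
  wetland: impassable
  other_land:
    mode: walking
    speed_kmh: 2.5
  river_barrier: impassable
  boat_route:
    mode: boat
    speed_kmh: 15.0
  major_road:
    mode: walking
    speed_kmh: 2.5
  major_road_residential:
    mode: walking
    speed_kmh: 2.5
  secondary_road:
    mode: walking
    speed_kmh: 2.5
  local_road_all:
    mode: walking
    speed_kmh: 2.5
  local_road_moto_bike:
    mode: walking
    speed_kmh: 2.5
  local_road_walk:
    mode: walking
    speed_kmh: 2.5
  water: impassable
cycling:
  forestland:
    mode: walking
    speed_kmh: 1.0
  grassland:
    mode: bicycle
    speed_kmh: 7.0
  cropland:
    mode: walking
    speed_kmh: 1.7
  settlement:
    mode: bicycle
    speed_kmh: 7.0
  wetland: impassable
  other_land:
    mode: bicycle
    speed_kmh: 7.0
  river_barrier: impassable
  boat_route:
    mode: boat
    speed_kmh: 15.0
  major_road:
    mode: bicycle
    speed_kmh: 10.0
  major_road_residential:
    mode: bicycle
    speed_kmh: 10.0
  secondary_road:
    mode: bicycle
    speed_kmh: 10.0
  local_road_all:
    mode: bicycle
    speed_kmh: 10.0
  local_road_moto_bike:
    mode: bicycle
    speed_kmh: 10.0
  local_road_walk:
    mode: walking
    speed_kmh: 2.5
  water: impassable
motorcycle:
  forestland:
    mode: walking
    speed_kmh: 1.0
  grassland:
    mode: motorcycle
    speed_kmh: 7.0
  cropland:
    mode: walking
    speed_kmh: 1.7
  settlement:
    mode: motorcycle
    speed_kmh: 7.0
  wetland: impassable
  other_land:
    mode: motorcycle
    speed_kmh: 7.0
  river_barrier: impassable
  boat_route:
    mode: boat
    speed_kmh: 15.0
  major_road:
    mode: motorcycle
    speed_kmh: 40.200000000000003
  major_road_residential:
    mode: motorcycle
    speed_kmh: 26.199999999999999
  secondary_road:
    mode: motorcycle
    speed_kmh: 35.200000000000003
  local_road_all:
    mode: motorcycle
    speed_kmh: 15.0
  local_road_moto_bike:
    mode: motorcycle
    speed_kmh: 15.0
  local_road_walk:
    mode: walking
    speed_kmh: 2.5
  water: impassable
car:
  forestland:
    mode: walking
    speed_kmh: 1.0
  grassland:
    mode: walking
    speed_kmh: 1.7
  cropland:
    mode: walking
    speed_kmh: 1.7
  settlement:
    mode: walking
    speed_kmh: 2.5
  wetland: impassable
  other_land:
    mode: walking
    speed_kmh: 2.5
  river_barrier: impassable
  boat_route:
    mode: boat
    speed_kmh: 15.0
  major_road:
    mode: car
    speed_kmh: 50.0
  major_road_residential:
    mode: car
    speed_kmh: 30.0
  secondary_road:
    mode: car
    speed_kmh: 40.0
  local_road_all:
    mode: car
    speed_kmh: 15.0
  local_road_moto_bike:
    mode: walking
    speed_kmh: 2.5
  local_road_walk:
    mode: walking
    speed_kmh: 2.5
  water: impassable
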